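#' Simplify scorer vocabularies to the 4-class stage set
#'
#' Reference hypnograms are scored either with the R&K vocabulary
#' (`W, S1..S4, R, MT`) or the AASM vocabulary (`W, N1, N2, N3, R, ?`). Both
#' collapse onto the classifier's four classes: S1/S2 and N1/N2 become
#' `N1N2`, S3/S4 and N3 become `N3`, Wake and REM pass through unchanged,
#' and movement time / unscorable symbols become `UNSCORED`.
#'
#' @param labels character vector of scorer symbols.
#' @param scheme `"RK"` or `"AASM"`.
#' @return factor over `WAKE, N1N2, N3, REM, UNSCORED`.
#' @export
simplify_labels <- function(labels, scheme = c("AASM", "RK")) {
  scheme <- match.arg(toupper(scheme), c("AASM", "RK"))
  map <- if (scheme == "AASM")
    c(W = "WAKE", N1 = "N1N2", N2 = "N1N2", N3 = "N3", R = "REM", "?" = "UNSCORED")
  else
    c(W = "WAKE", S1 = "N1N2", S2 = "N1N2", S3 = "N3", S4 = "N3", R = "REM",
      MT = "UNSCORED")
  labels <- toupper(as.character(labels))
  bad <- setdiff(unique(labels), names(map))
  if (length(bad))
    abort_validation(sprintf("unknown %s label(s): %s", scheme,
                             paste(bad, collapse = ", ")))
  stage_factor(unname(map[labels]))
}

merged_hypnogram <- function(h, labels, vocab) {
  out <- h
  out$values <- factor(as.character(labels), levels = vocab)
  out
}

#' Merge stages for the 3-class and 2-class tasks
#'
#' The 4-class output can be evaluated on simplified tasks: `"three"` merges
#' N1-N2 and N3 into a single `NREM` class (Wake / NREM / REM), `"two"`
#' merges N1-N2, N3 and REM into `SLEEP` (Wake / Sleep). `"four"` is the
#' identity.
#'
#' @param h a [hypnogram()] over the 4-class vocabulary.
#' @param task `"four"`, `"three"` or `"two"`.
#' @return a hypnogram over the task's vocabulary (UNSCORED passes through).
#' @export
merge_task <- function(h, task = c("four", "three", "two")) {
  task <- match.arg(task)
  if (task == "four") return(h)
  lab <- as.character(h$values)
  if (task == "three") {
    lab[lab %in% c("N1N2", "N3")] <- "NREM"
    merged_hypnogram(h, lab, c("WAKE", "NREM", "REM", "UNSCORED"))
  } else {
    lab[lab %in% c("N1N2", "N3", "REM")] <- "SLEEP"
    merged_hypnogram(h, lab, c("WAKE", "SLEEP", "UNSCORED"))
  }
}

#' Pooled confusion matrix between reference and predicted hypnograms
#'
#' Counts epochs with the reference stage on rows and the predicted stage on
#' columns. Epochs whose reference is `UNSCORED` are excluded, as are (when
#' `restrict_lights_off = TRUE` and the reference carries a lights-off
#' interval) epochs outside that interval — performance is assessed only
#' where the reference scorer assessed the night. Matrices from several
#' recordings may be added; pooling is exactly additive.
#'
#' @param ref reference [hypnogram()].
#' @param pred predicted hypnogram on the same epoch grid (same start time,
#'   same length).
#' @param restrict_lights_off restrict counting to the reference lights-off
#'   interval when present.
#' @return a `"confusion_matrix"`: K x K integer matrix, reference on rows.
#' @export
confusion <- function(ref, pred, restrict_lights_off = TRUE) {
  if (n_epochs(ref) != n_epochs(pred))
    abort_validation("ref and pred must have the same number of epochs")
  if (abs(ref$start_time - pred$start_time) > 1e-6)
    abort_validation("ref and pred must share the epoch grid (same start time)")
  vocab <- setdiff(levels(ref$values), "UNSCORED")
  keep <- as.character(ref$values) != "UNSCORED" &
          as.character(pred$values) != "UNSCORED"
  if (restrict_lights_off && !is.null(ref$lights_off)) {
    st <- epoch_start(ref, seq_len(n_epochs(ref)) - 1L)
    keep <- keep & st >= ref$lights_off[1] - 1e-9 & st < ref$lights_off[2] - 1e-9
  }
  if (!any(keep)) abort_validation("no comparable epochs between ref and pred")
  cm <- table(factor(as.character(ref$values)[keep], levels = vocab),
              factor(as.character(pred$values)[keep], levels = vocab))
  confusion_matrix(unclass(as.matrix(cm)))
}

#' @rdname confusion
#' @param counts K x K non-negative count matrix (reference on rows).
#' @export
confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-9))
    abort_validation("confusion counts must be a square non-negative integer matrix")
  if (is.null(rownames(counts))) rownames(counts) <- colnames(counts) <- STAGES[seq_len(nrow(counts))]
  structure(counts, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion matrix: %d classes, %d epochs>\n", nrow(x), sum(x)))
  print(unclass(x)); invisible(x)
}

#' @export
`+.confusion_matrix` <- function(e1, e2) confusion_matrix(unclass(e1) + unclass(e2))

kappa_from_counts <- function(cm) {
  tot <- sum(cm)
  po <- sum(diag(cm)) / tot
  pe <- sum((rowSums(cm) / tot) * (colSums(cm) / tot))
  if (abs(1 - pe) < .Machine$double.eps * 8) {
    warning("chance agreement is 1: kappa undefined", call. = FALSE)
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Agreement metrics from a pooled confusion matrix
#'
#' Computes overall accuracy (`trace / total`), Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)` with `p_e = sum_k (row_k/total)(col_k/total)`,
#' and per-class one-vs-rest metrics: each class in turn is taken as
#' positive and all others pooled as negative, giving prevalence,
#' sensitivity, specificity, positive predictive value, F1 and a binary
#' kappa per class.
#'
#' @param cm a [confusion_matrix()].
#' @param positive_class optional class name; when given, the 2 x 2
#'   one-vs-rest collapse for that class is returned instead of the full
#'   report.
#' @return a `"metric_report"` list: `accuracy`, `kappa`, `n`, and
#'   `per_class` data frame (proportions on `[0, 1]`).
#' @export
stage_metrics <- function(cm, positive_class = NULL) {
  if (!inherits(cm, "confusion_matrix")) cm <- confusion_matrix(cm)
  tot <- sum(cm)
  if (tot <= 0) abort_validation("confusion matrix has no epochs")
  classes <- rownames(cm)
  one_vs_rest <- function(k) {
    tp <- cm[k, k]; fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp; tn <- tot - tp - fn - fp
    b <- matrix(c(tp, fn, fp, tn), 2, 2,
                dimnames = list(c("pos", "neg"), c("pos", "neg")))
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (isTRUE(ppv + sens > 0)) 2 * ppv * sens / (ppv + sens) else NA_real_
    list(binary = confusion_matrix(b), prevalence = (tp + fn) / tot,
         sensitivity = sens, specificity = spec, ppv = ppv, f1 = f1,
         kappa = kappa_from_counts(b))
  }
  if (!is.null(positive_class)) {
    if (!positive_class %in% classes)
      abort_validation(sprintf("unknown positive class '%s'", positive_class))
    o <- one_vs_rest(positive_class)
    b <- o$binary
    return(structure(list(accuracy = sum(diag(b)) / tot, kappa = o$kappa, n = tot,
                          per_class = data.frame(class = positive_class,
                                                 prevalence = o$prevalence,
                                                 sensitivity = o$sensitivity,
                                                 specificity = o$specificity,
                                                 ppv = o$ppv, f1 = o$f1,
                                                 kappa = o$kappa)),
                     class = "metric_report"))
  }
  per <- lapply(classes, one_vs_rest)
  structure(list(
    accuracy = sum(diag(cm)) / tot,
    kappa = kappa_from_counts(cm),
    n = tot,
    per_class = data.frame(
      class = classes,
      prevalence = vapply(per, `[[`, 0, "prevalence"),
      sensitivity = vapply(per, `[[`, 0, "sensitivity"),
      specificity = vapply(per, `[[`, 0, "specificity"),
      ppv = vapply(per, `[[`, 0, "ppv"),
      f1 = vapply(per, `[[`, 0, "f1"),
      kappa = vapply(per, `[[`, 0, "kappa"))
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("accuracy %.1f%%, kappa %.3f (%s), n = %d epochs\n",
              100 * x$accuracy, x$kappa, kappa_band(x$kappa), x$n))
  df <- x$per_class
  for (col in c("prevalence", "sensitivity", "specificity", "ppv", "f1"))
    df[[col]] <- sprintf("%.1f%%", 100 * df[[col]])
  df$kappa <- sprintf("%.2f", df$kappa)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Landis–Koch agreement band for a kappa value
#'
#' Bands with inclusive lower bounds: below 0.20 "slight", 0.20–0.40 "fair",
#' 0.40–0.60 "moderate", 0.60–0.80 "substantial", 0.80 and above
#' "almost perfect".
#'
#' @param k kappa value (`k <= 1`).
#' @return character band label.
#' @export
kappa_band <- function(k) {
  if (any(k > 1 + 1e-12)) abort_validation("kappa cannot exceed 1")
  cuts <- c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf)
  labs <- c("slight", "fair", "moderate", "substantial", "almost perfect")
  labs[findInterval(k, cuts, left.open = FALSE)]
}

#' Descriptive statistic with the normality-dependent convention
#'
#' A Shapiro–Wilk test at p = 0.05 picks the reporting form: normal samples
#' are summarised as `mean (SD)`, non-normal (or degenerate-variance)
#' samples as `median {Q1, Q3}` with quartiles by linear interpolation
#' between order statistics.
#'
#' @param values numeric sample (`n >= 3` for the test; smaller samples are
#'   echoed raw).
#' @param digits significant digits in the formatted string.
#' @return list with `form` (`"mean_sd"`, `"median_iqr"` or `"raw"`), the
#'   relevant statistics, and a formatted `text`.
#' @export
describe_sample <- function(values, digits = 3) {
  values <- values[is.finite(values)]
  fmt <- function(v) format(signif(v, digits), trim = TRUE)
  if (length(values) < 3)
    return(list(form = "raw", values = values,
                text = paste(fmt(values), collapse = ", ")))
  normal <- FALSE
  if (var(values) > 0) {
    sw <- shapiro.test(if (length(values) > 5000) sample(values, 5000) else values)
    normal <- sw$p.value >= 0.05
  }
  if (normal) {
    m <- mean(values); s <- sd(values)
    list(form = "mean_sd", mean = m, sd = s,
         text = sprintf("%s (%s)", fmt(m), fmt(s)))
  } else {
    q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
    list(form = "median_iqr", median = q[2], q1 = q[1], q3 = q[3],
         text = sprintf("%s {%s, %s}", fmt(q[2]), fmt(q[1]), fmt(q[3])))
  }
}

#' Signed-rank equivalence test for paired performance differences
#'
#' Two staging methods compared on the same recordings yield paired
#' per-recording kappa differences. The Hodges–Lehmann point estimate is the
#' median of the Walsh averages `(d_i + d_j)/2, i <= j`; the 95% confidence
#' interval inverts the Wilcoxon signed-rank test (exact null quantiles for
#' `n <= 25`, normal approximation beyond; zero differences dropped, ties
#' mid-ranked through the Walsh-average construction). The methods are
#' declared equivalent exactly when the CI lies fully inside the margin
#' `[-delta, delta]`.
#'
#' @param diffs numeric vector of paired differences (e.g. kappa_A - kappa_B
#'   per recording).
#' @param delta non-negative equivalence margin.
#' @param conf_level confidence level of the interval (default 0.95).
#' @return an `"equivalence_result"` list: `estimate`, `ci_low`, `ci_high`,
#'   `delta`, `n`, `verdict`.
#' @export
equivalence_test <- function(diffs, delta, conf_level = 0.95) {
  stopifnot_scalar_num(delta, "delta", lower = 0)
  diffs <- diffs[is.finite(diffs)]
  nz <- diffs[diffs != 0]
  n <- length(nz)
  if (n == 0L) {
    if (length(diffs) == 0L) abort_validation("no non-missing paired differences")
    res <- list(estimate = 0, ci_low = 0, ci_high = 0)
  } else {
    if (length(diffs) < 6L)
      abort_validation("need at least 6 non-missing pairs for a 95% CI")
    w <- outer(nz, nz, `+`)[upper.tri(matrix(0, n, n), diag = TRUE)] / 2
    w <- sort(w)
    m <- n * (n + 1) / 2
    alpha <- 1 - conf_level
    if (n <= 25) {
      qu <- qsignrank(alpha / 2, n)
      if (qu == 0) qu <- 1
    } else {
      qu <- floor(m / 2 - stats::qnorm(1 - alpha / 2) *
                    sqrt(n * (n + 1) * (2 * n + 1) / 24))
      qu <- max(1, qu)
    }
    res <- list(estimate = median(w), ci_low = w[qu], ci_high = w[m - qu + 1])
  }
  res$delta <- delta
  res$n <- n
  res$verdict <- if (res$ci_low >= -delta && res$ci_high <= delta)
    "equivalent" else "not-equivalent"
  structure(res, class = "equivalence_result")
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf("Hodges-Lehmann estimate %.4f, 95%% CI [%.4f, %.4f]\n",
              x$estimate, x$ci_low, x$ci_high))
  cat(sprintf("margin [%.4g, %.4g] -> %s (n = %d non-zero pairs)\n",
              -x$delta, x$delta, x$verdict, x$n))
  invisible(x)
}

#' Published pooled validation confusion counts
#'
#' The pooled 4-class epoch counts reported by a large wearable-vs-PSG
#' validation study of a PPG + accelerometer sleep stager (hold-out set of
#' 394 clinical and healthy recordings, 30-s epochs, reference scorer on
#' rows). Shipped as a worked example and as a regression anchor for
#' [stage_metrics()]: all of that study's printed derived values
#' (prevalences, sensitivities, PPVs, per-class one-vs-rest kappas)
#' reproduce from these counts.
#'
#' @return a 4 x 4 [confusion_matrix()].
#' @export
published_pooled_confusion <- function() {
  confusion_matrix(matrix(
    c(53076, 15179,   216,  1018,
      12657, 165414, 12901,  8015,
        549, 23895,  41326,   158,
       1224, 15080,    509, 42007),
    nrow = 4, byrow = TRUE, dimnames = list(STAGES, STAGES)))
}
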