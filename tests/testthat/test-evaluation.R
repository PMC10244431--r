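test_that("scorer vocabularies simplify onto the 4-class set", {
  expect_identical(as.character(simplify_labels(c("W", "N1", "N2", "N3", "R"), "AASM")),
                   c("WAKE", "N1N2", "N1N2", "N3", "REM"))
  expect_identical(as.character(simplify_labels(c("W", "S1", "S2", "S3", "S4", "R", "MT"), "RK")),
                   c("WAKE", "N1N2", "N1N2", "N3", "N3", "REM", "UNSCORED"))
  expect_identical(as.character(simplify_labels("S4", "RK")), "N3")
  expect_length(simplify_labels(character(0), "AASM"), 0)
  expect_error(simplify_labels("S9", "RK"), class = "wearstage_validation_error",
               regexp = "S9")
})

test_that("class merges produce the 3-class and 2-class tasks", {
  h <- hypnogram(c("WAKE", "N1N2", "N3", "REM"))
  expect_identical(as.character(merge_task(h, "three")$values),
                   c("WAKE", "NREM", "NREM", "REM"))
  expect_identical(as.character(merge_task(h, "two")$values),
                   c("WAKE", "SLEEP", "SLEEP", "SLEEP"))
  expect_identical(merge_task(h, "four"), h)
})

test_that("confusion counts respect scoring restrictions and pool additively", {
  set.seed(31)
  labs <- function(n) sample(STAGES <- c("WAKE", "N1N2", "N3", "REM"), n, TRUE)
  ref <- hypnogram(labs(100))
  cm <- confusion(ref, ref, restrict_lights_off = FALSE)
  expect_equal(sum(diag(cm)), 100)
  expect_equal(sum(cm) - sum(diag(cm)), 0)

  # lights-off restriction drops the epochs before t_on
  ref_lo <- hypnogram(labs(100), lights_off = c(300, 3000))
  pred <- hypnogram(labs(100))
  cm_lo <- confusion(ref_lo, pred)
  expect_equal(sum(cm_lo), 90)

  # UNSCORED reference epochs are excluded
  v <- labs(50); v[1:5] <- "UNSCORED"
  cm_u <- confusion(hypnogram(v), hypnogram(labs(50)), restrict_lights_off = FALSE)
  expect_equal(sum(cm_u), 45)

  # pooling over recordings equals the sum of per-recording matrices
  prs <- lapply(1:5, function(i) list(r = hypnogram(labs(60)), p = hypnogram(labs(60))))
  pooled_cells <- Reduce(`+`, lapply(prs, function(x)
    confusion(x$r, x$p, restrict_lights_off = FALSE)))
  all_ref <- hypnogram(unlist(lapply(prs, function(x) as.character(x$r$values))))
  all_pred <- hypnogram(unlist(lapply(prs, function(x) as.character(x$p$values))))
  expect_equal(unclass(pooled_cells),
               unclass(confusion(all_ref, all_pred, restrict_lights_off = FALSE)))

  expect_error(confusion(hypnogram(rep("UNSCORED", 3)), hypnogram(labs(3)),
                         restrict_lights_off = FALSE),
               class = "wearstage_validation_error")
})

test_that("kappa matches a brute-force p_o/p_e computation and e1071 on random matrices", {
  skip_if_not_installed("e1071")
  brute_kappa <- function(m) {
    tot <- sum(m)
    po <- sum(diag(m)) / tot
    pe <- 0
    for (k in seq_len(nrow(m))) pe <- pe + (sum(m[k, ]) / tot) * (sum(m[, k]) / tot)
    (po - pe) / (1 - pe)
  }
  set.seed(77)
  for (i in 1:200) {
    k <- sample(2:5, 1)
    m <- matrix(rpois(k * k, sample(c(2, 10, 50), 1)), k, k)
    if (sum(m) == 0 || abs(1 - sum(rowSums(m) * colSums(m)) / sum(m)^2) < 1e-12) next
    dimnames(m) <- list(paste0("c", 1:k), paste0("c", 1:k))
    rep <- stage_metrics(confusion_matrix(m))
    expect_equal(rep$kappa, brute_kappa(m), tolerance = 1e-12)
    expect_equal(rep$kappa, e1071::classAgreement(m)$kappa, tolerance = 1e-8)
    expect_equal(rep$accuracy, sum(diag(m)) / sum(m), tolerance = 1e-12)
  }
})

test_that("metric edge cases: perfect agreement, degenerate marginals, F1 identity", {
  m <- confusion_matrix(matrix(c(40, 0, 0, 60), 2, 2,
                               dimnames = list(c("a", "b"), c("a", "b"))))
  rep <- stage_metrics(m)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$kappa, 1)
  # F1 is the harmonic mean of PPV and sensitivity for every class
  sr <- small_night()
  set.seed(8)
  pred <- hypnogram(sample(c("WAKE", "N1N2", "N3", "REM"),
                           n_epochs(sr$recording$hypnogram), TRUE))
  rep2 <- stage_metrics(confusion(sr$recording$hypnogram, pred))
  with(rep2$per_class, expect_equal(f1, 2 * ppv * sensitivity / (ppv + sensitivity)))

  deg <- matrix(c(5, 0, 0, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  w <- capture_warnings(repd <- stage_metrics(confusion_matrix(deg)))
  expect_true(any(grepl("undefined", w)))  # overall + per-class collapses warn
  expect_true(is.na(repd$kappa))
})

test_that("kappa bands follow the inclusive lower-bound convention", {
  expect_identical(kappa_band(0.638), "substantial")
  expect_identical(kappa_band(0.40), "moderate")
  expect_identical(kappa_band(-0.1), "slight")
  expect_identical(kappa_band(c(0.19999, 0.2, 0.6, 0.8, 1)),
                   c("slight", "fair", "substantial", "almost perfect",
                     "almost perfect"))
  expect_error(kappa_band(1.2), class = "wearstage_validation_error")
})

test_that("descriptive statistics switch form on a Shapiro-Wilk test", {
  set.seed(5)
  heavy <- rcauchy(1000)
  expect_identical(describe_sample(heavy)$form, "median_iqr")
  normal <- rnorm(200)
  expect_identical(describe_sample(normal)$form, "mean_sd")
  d3 <- describe_sample(c(1, 2, 3, 1, 2, 3, 1, 2, 3))  # non-normal ties
  expect_identical(d3$form, "median_iqr")
  # linear-interpolation quartiles
  expect_equal(unname(quantile(c(1, 2, 3), c(.25, .75), type = 7)), c(1.5, 2.5))
  expect_identical(describe_sample(rep(4, 10))$form, "median_iqr")
  expect_identical(describe_sample(c(1, 2))$form, "raw")
})

# exhaustive enumeration of the signed-rank null: quantile k such that the
# CI [W_(k), W_(M+1-k)] inverts the exact two-sided test at alpha = 0.05
enum_signrank_ci <- function(d, conf = 0.95) {
  d <- d[d != 0]
  n <- length(d)
  stats <- integer(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[1:n]
    stats[m + 1] <- sum(seq_len(n)[signs == 1])  # W+ over all sign patterns
  }
  cdf <- cumsum(tabulate(stats + 1L, nbins = n * (n + 1) / 2 + 1)) / 2^n
  alpha <- 1 - conf
  qu <- min(which(cdf >= alpha / 2)) - 1L  # smallest q with P(W+ <= q) >= alpha/2
  if (qu < 1) qu <- 1
  w <- sort(outer(d, d, `+`)[upper.tri(diag(n), diag = TRUE)] / 2)
  m <- n * (n + 1) / 2
  c(w[qu], w[m - qu + 1])
}

test_that("equivalence CI matches exhaustive signed-rank enumeration and wilcox.test", {
  set.seed(12)
  for (rep in 1:6) {
    n <- sample(8:12, 1)
    d <- rnorm(n, 0.01, 0.05)  # continuous: tie-free, exact branch everywhere
    res <- equivalence_test(d, delta = 0.1)
    expect_equal(c(res$ci_low, res$ci_high), enum_signrank_ci(d), tolerance = 1e-12)
    wt <- suppressWarnings(wilcox.test(d, conf.int = TRUE, conf.level = 0.95,
                                       exact = TRUE))
    expect_equal(res$ci_low, unname(wt$conf.int[1]), tolerance = 1e-9)
    expect_equal(res$ci_high, unname(wt$conf.int[2]), tolerance = 1e-9)
    expect_equal(res$estimate, unname(wt$estimate), tolerance = 1e-9)
  }
})

test_that("equivalence verdicts follow the CI-in-margin rule", {
  res0 <- equivalence_test(rep(0, 10), delta = 0.021)
  expect_equal(c(res0$ci_low, res0$ci_high), c(0, 0))
  expect_identical(res0$verdict, "equivalent")

  set.seed(3)
  d <- rnorm(20, 0, 0.004)
  res <- equivalence_test(d, delta = 0.021)
  expect_identical(res$verdict, "equivalent")
  res_sh <- equivalence_test(d + 2 * 0.021, delta = 0.021)
  expect_identical(res_sh$verdict, "not-equivalent")
  expect_true(res$ci_low <= res$estimate && res$estimate <= res$ci_high)
  expect_error(equivalence_test(c(0.1, 0.2), delta = 0.1),
               class = "wearstage_validation_error")
})

test_that("the 95% signed-rank CI achieves nominal coverage on symmetric samples", {
  set.seed(2024)
  n_sim <- 2000
  hits <- 0L
  for (i in seq_len(n_sim)) {
    d <- rnorm(12, mean = 0.3)
    res <- equivalence_test(d, delta = 1)
    hits <- hits + (res$ci_low <= 0.3 && 0.3 <= res$ci_high)
  }
  expect_gt(hits / n_sim, 0.95 - 0.015)
  expect_lt(hits / n_sim, 0.95 + 0.015)
})

test_that("published pooled confusion counts are internally consistent", {
  cm <- published_pooled_confusion()
  expect_equal(unname(rowSums(cm)), c(69489, 198987, 65928, 58820))
  expect_equal(sum(diag(cm)), 301823)
})
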