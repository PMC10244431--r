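#' Per-epoch motion features for rest/active discrimination
#'
#' Four 1-s base features are computed from the triaxial signal and each is
#' aggregated per 30-s epoch with four statistics (mean, SD, maximum, 95th
#' percentile), giving a frozen 16-value vector per epoch in base-feature-
#' major order: `zc_{mean,sd,max,p95}, period_{...}, vert_{...},
#' cadence_{...}`. The base features are: zero crossings — sign changes of
#' each 0.25–3 Hz band-passed axis, summed over axes; periodicity — maximum
#' normalised autocorrelation of the acceleration magnitude at lags
#' 0.25–2 s over a 4-s window centred on the second; vertical acceleration
#' — absolute deviation from 1 g of the projection of the 1-s mean
#' acceleration onto the low-pass gravity axis; motion cadence — the
#' frequency (Hz) of the autocorrelation peak, 0 when periodicity < 0.3.
#'
#' @param acc a [triaxial_signal()] with at least 30 s of data.
#' @return a `"motion_features"`: `values` (E x 16 matrix), `invalid`
#'   (logical, epochs with missing samples get zero features), `start_time`,
#'   `clock_id`.
#' @export
compute_motion_features <- function(acc) {
  fs <- as.integer(round(acc$fs))
  if (abs(acc$fs - fs) > 1e-9 || fs < 4) abort_validation("fs must be an integer >= 4 Hz")
  n <- ncol(acc$samples)
  if (n < EPOCH_SEC * fs) abort_validation("need at least 30 s of accelerometer data")
  n_sec <- n %/% fs
  E <- as.integer(ceiling(n_sec / EPOCH_SEC))
  x <- acc$samples[, seq_len(n_sec * fs), drop = FALSE]

  bp <- signal::butter(2, c(0.25, 3) / (fs / 2), type = "pass")
  lp <- signal::butter(2, 1 / (fs / 2), type = "low")
  xf <- t(apply(x, 1, function(a) filtfilt_pad(bp, a, fs)))
  xl <- t(apply(x, 1, function(a) filtfilt_pad(lp, a, fs)))

  # zero crossings per second, summed over axes
  zc_axis <- function(a) {
    s <- sign(a); s[s == 0] <- 1
    ch <- c(0, abs(diff(s)) > 0)
    colSums(matrix(ch, nrow = fs))
  }
  zc <- zc_axis(xf[1, ]) + zc_axis(xf[2, ]) + zc_axis(xf[3, ])

  # vertical acceleration: 1-s mean projected on the low-pass gravity axis
  sec_mean <- function(m) colMeans(matrix(m, nrow = fs))
  mx <- sec_mean(x[1, ]); my <- sec_mean(x[2, ]); mz <- sec_mean(x[3, ])
  gx <- sec_mean(xl[1, ]); gy <- sec_mean(xl[2, ]); gz <- sec_mean(xl[3, ])
  gn <- pmax(sqrt(gx^2 + gy^2 + gz^2), 1e-9)
  vert <- abs((mx * gx + my * gy + mz * gz) / gn - 1)

  # periodicity & cadence from the magnitude autocorrelation in a centred
  # 4-s window (clamped at the recording edges)
  mag <- sqrt(colSums(x^2))
  wlen <- 4L * fs
  starts <- pmin(pmax((seq_len(n_sec) - 1L) * fs - (wlen - fs) %/% 2L, 0L),
                 n_sec * fs - wlen)
  W <- matrix(mag[outer(1:wlen, starts, `+`)], nrow = n_sec, byrow = TRUE)
  W <- W - rowMeans(W)
  denom <- pmax(rowSums(W * W), 1e-12)
  lags <- seq.int(max(1L, round(0.25 * fs)), 2L * fs)
  best_rho <- rep(-1, n_sec); best_lag <- rep(NA_integer_, n_sec)
  for (l in lags) {
    num <- rowSums(W[, 1:(wlen - l), drop = FALSE] * W[, (l + 1):wlen, drop = FALSE])
    rho <- num / denom
    upd <- rho > best_rho
    best_rho[upd] <- rho[upd]; best_lag[upd] <- l
  }
  periodicity <- pmax(best_rho, 0)
  cadence <- ifelse(periodicity >= 0.3, fs / best_lag, 0)

  agg <- function(v) {
    pad <- c(v, rep(NA_real_, E * EPOCH_SEC - n_sec))
    m <- matrix(pad, nrow = EPOCH_SEC)
    cbind(mean = apply(m, 2, mean), sd = apply(m, 2, function(z) {
      z <- z[!is.na(z)]; if (length(z) > 1) sd(z) else 0
    }), max = apply(m, 2, max), p95 = apply(m, 2, quantile, 0.95, na.rm = TRUE,
                                            names = FALSE))
  }
  vals <- cbind(agg(zc), agg(periodicity), agg(vert), agg(cadence))
  colnames(vals) <- as.vector(outer(c("mean", "sd", "max", "p95"),
                                    c("zc", "period", "vert", "cadence"),
                                    function(s, f) paste(f, s, sep = "_")))
  invalid <- apply(vals, 1, function(r) any(!is.finite(r)))
  vals[invalid, ] <- 0
  structure(list(values = vals, invalid = invalid,
                 start_time = acc$start_time, clock_id = acc$clock_id),
            class = "motion_features")
}

#' Bayesian linear discriminant for rest vs. active epochs
#'
#' Maximum-likelihood Gaussian class means with a pooled (shared)
#' covariance, regularised by `eps * mean(diag) * I` so degenerate synthetic
#' features cannot make it singular; class priors from the label
#' frequencies. The posterior probability of "rest" under the two-Gaussian
#' model is used as the per-epoch rest likelihood.
#'
#' @param feats a `"motion_features"` object or an E x 16 matrix.
#' @param labels logical (or `"rest"`/`"active"`) vector, `TRUE` = rest.
#' @param eps covariance regularisation fraction.
#' @return a `"rest_lda"` model with a [predict()] method returning
#'   `P(rest | features)`.
#' @export
train_rest_discriminant <- function(feats, labels, eps = 1e-4) {
  X <- if (inherits(feats, "motion_features")) feats$values else as.matrix(feats)
  if (is.character(labels) || is.factor(labels)) labels <- as.character(labels) == "rest"
  labels <- as.logical(labels)
  if (length(labels) != nrow(X)) abort_validation("one label per epoch required")
  if (length(unique(labels)) < 2L)
    abort_validation("both classes (rest and active) must be present")
  mu <- rbind(rest = colMeans(X[labels, , drop = FALSE]),
              active = colMeans(X[!labels, , drop = FALSE]))
  ctr <- X - mu[2L - labels, , drop = FALSE]
  S <- crossprod(ctr) / (nrow(X) - 2)
  S <- S + eps * mean(diag(S)) * diag(ncol(X))
  structure(list(means = mu, cov = S, cov_inv = solve(S),
                 priors = c(rest = mean(labels), active = mean(!labels)),
                 feature_names = colnames(X)),
            class = "rest_lda")
}

#' @export
predict.rest_lda <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "motion_features")) newdata$values else as.matrix(newdata)
  # log N(x; mu_k, S) + log prior, shared covariance -> linear discriminant
  lp <- sapply(c("rest", "active"), function(k) {
    d <- sweep(X, 2, object$means[k, ])
    -0.5 * rowSums((d %*% object$cov_inv) * d) + log(object$priors[[k]])
  })
  if (is.null(dim(lp))) lp <- matrix(lp, nrow = 1)
  1 / (1 + exp(lp[, 2] - lp[, 1]))
}

#' @export
print.rest_lda <- function(x, ...) {
  cat(sprintf("<rest/active linear discriminant: %d features, priors %.2f/%.2f>\n",
              ncol(x$means), x$priors[1], x$priors[2]))
  invisible(x)
}

#' Serialize / load a rest discriminant as JSON
#' @param disc a `"rest_lda"`.
#' @param path JSON file path.
#' @export
save_rest_discriminant <- function(disc, path) {
  jsonlite::write_json(list(means = disc$means, cov = disc$cov,
                            priors = as.list(disc$priors),
                            feature_names = disc$feature_names),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_rest_discriminant
#' @export
load_rest_discriminant <- function(path) {
  j <- jsonlite::fromJSON(path)
  S <- as.matrix(j$cov)
  means <- as.matrix(j$means); rownames(means) <- c("rest", "active")
  colnames(means) <- colnames(S) <- rownames(S) <- j$feature_names
  structure(list(means = means, cov = S, cov_inv = solve(S),
                 priors = unlist(j$priors), feature_names = j$feature_names),
            class = "rest_lda")
}

#' @rdname save_rest_discriminant
#' @details `default_rest_discriminant()` returns the discriminant shipped
#'   with the package, trained on simulator-labelled synthetic nights (no
#'   clinically trained weights are distributed).
#' @export
default_rest_discriminant <- function() {
  load_rest_discriminant(system.file("extdata", "rest_lda_synthetic.json",
                                     package = "wearstage", mustWork = TRUE))
}

#' Segment the resting period of a night
#'
#' Applies the discriminant to per-epoch motion features, flags epochs with
#' rest likelihood at or above the threshold (epochs below the
#' pre-determined 30% are excluded from staging), and delimits the main
#' resting period from the start of the first to the end of the last rest
#' epoch. Epochs with invalid features count as active.
#'
#' @param feats a `"motion_features"`.
#' @param disc a `"rest_lda"` (default: the shipped synthetic-trained one).
#' @param threshold rest-likelihood threshold (default 0.30).
#' @return a `"rest_profile"`: `likelihood` and `rest` ([epoch_series()]),
#'   `main_rest` (`c(t0, t1)` seconds or `NULL`), `threshold`.
#' @export
segment_rest <- function(feats, disc = default_rest_discriminant(),
                         threshold = 0.30) {
  lik <- predict(disc, feats)
  lik[feats$invalid] <- 0
  flag <- lik >= threshold
  es <- function(v) epoch_series(v, start_time = feats$start_time,
                                 clock_id = feats$clock_id)
  main_rest <- NULL
  if (any(flag)) {
    i0 <- which(flag)[1] - 1L; i1 <- max(which(flag))
    main_rest <- feats$start_time + EPOCH_SEC * c(i0, i1)
  }
  structure(list(likelihood = es(lik), rest = es(flag),
                 main_rest = main_rest, threshold = threshold),
            class = "rest_profile")
}

# epochs inside the main resting period (logical, length E)
in_main_rest <- function(profile) {
  E <- length(profile$rest$values)
  if (is.null(profile$main_rest)) return(rep(FALSE, E))
  st <- epoch_start(profile$rest, seq_len(E) - 1L)
  st >= profile$main_rest[1] - 1e-9 & st < profile$main_rest[2] - 1e-9
}
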