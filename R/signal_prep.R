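#' Beat and interval series containers
#'
#' A `beat_series` holds detected beat instants on a device clock together
#' with a per-beat quality flag (`retained` vs. motion-discarded); an
#' `ibi_series` holds the interbeat intervals between consecutive retained
#' beats, each anchored at the time of the later beat, with a plausibility
#' flag (`valid` when the interval lies in the 0.27–2.0 s band, i.e.
#' roughly 30–220 bpm; longer bridges across discarded beats are invalid
#' and never interpolated).
#'
#' @param times numeric beat times (s), sorted.
#' @param retained logical per-beat flag.
#' @param clock_id clock label.
#' @return a `"beat_series"`.
#' @export
beat_series <- function(times, retained = rep(TRUE, length(times)),
                        clock_id = "wearable") {
  if (is.unsorted(times)) abort_validation("beat times must be sorted")
  if (length(retained) != length(times))
    abort_validation("`retained` must match `times` in length")
  if (is.unsorted(times[retained], strictly = TRUE))
    abort_validation("retained beat times must be strictly increasing")
  structure(list(times = as.numeric(times), retained = retained,
                 clock_id = clock_id),
            class = "beat_series")
}

#' @rdname beat_series
#' @param bs a `beat_series`.
#' @export
retained_beats <- function(bs) bs$times[bs$retained]

IBI_BAND <- c(0.27, 2.0)

# forward-backward filtering with odd-reflection padding: r-signal's
# filtfilt pads with zeros, which injects edge transients even for a
# constant input; reflecting ~3 s of signal at each end removes them
filtfilt_pad <- function(bf, x, fs) {
  n <- length(x)
  # route the mean through the filter's exact DC gain so a constant signal
  # maps to a constant with no startup transient at all
  dc <- sum(bf$b) / sum(bf$a)
  m <- mean(x)
  x0 <- x - m
  p <- min(n - 1L, as.integer(3 * fs))
  if (p < 1L) return(signal::filtfilt(bf, x0) + m * dc^2)
  head_ref <- 2 * x0[1] - x0[(p + 1L):2L]
  tail_ref <- 2 * x0[n] - x0[(n - 1L):(n - p)]
  y <- signal::filtfilt(bf, c(head_ref, x0, tail_ref))
  y[(p + 1L):(p + n)] + m * dc^2
}

#' Activity counts per 30-s epoch
#'
#' Reimplements the classic actigraphy count recipe: each axis is low-pass
#' filtered (3rd-order Butterworth, 1 Hz cutoff, applied forward-backward
#' so bursts are not phase-shifted across window boundaries); per
#' non-overlapping 1-s window the gravity estimate is the mean absolute
#' value of the filtered axis; the 1-s count is the sum over axes and
#' samples of `max(|filtered sample| - gravity estimate, 0)`; the 30-s
#' count sums its thirty 1-s counts. Counts are computed over the whole
#' recording and never zeroed outside rest: the classifier itself uses
#' high counts as evidence of Wake.
#'
#' @param acc a [triaxial_signal()] with integer `fs >= 4` Hz.
#' @return an [epoch_series()] of non-negative counts on the
#'   accelerometer's clock.
#' @export
compute_activity_counts <- function(acc) {
  fs <- acc$fs
  if (fs < 4) abort_validation("accelerometer fs must be >= 4 Hz to design the 1 Hz filter")
  if (abs(fs - round(fs)) > 1e-9) abort_validation("accelerometer fs must be an integer")
  fs <- as.integer(round(fs))
  n <- ncol(acc$samples)
  if (n < fs) abort_validation("need at least 1 s of accelerometer data")
  n_sec <- n %/% fs
  if (n_sec * fs < n)
    warning("partial trailing 1-s window dropped from activity counts", call. = FALSE)
  bf <- signal::butter(3, 1 / (fs / 2), type = "low")
  sec_counts <- numeric(n_sec)
  for (ax in 1:3) {
    f <- abs(filtfilt_pad(bf, acc$samples[ax, seq_len(n_sec * fs)], fs))
    m <- matrix(f, nrow = fs)
    grav <- colMeans(m)
    sec_counts <- sec_counts + colSums(pmax(sweep(m, 2, grav), 0))
  }
  n_ep <- n_sec %/% EPOCH_SEC
  if (n_ep * EPOCH_SEC < n_sec)
    warning("partial trailing 30-s epoch dropped from activity counts", call. = FALSE)
  counts <- colSums(matrix(sec_counts[seq_len(n_ep * EPOCH_SEC)], nrow = EPOCH_SEC))
  epoch_series(counts, start_time = acc$start_time, clock_id = acc$clock_id)
}

# per-second maximum deviation of the raw acceleration magnitude from 1 g,
# on the accelerometer's own 1-s grid starting at its start_time
acc_motion_per_second <- function(acc) {
  fs <- as.integer(round(acc$fs))
  n_sec <- ncol(acc$samples) %/% fs
  if (n_sec < 1L) return(list(t0 = acc$start_time, dev = numeric(0)))
  mag <- sqrt(colSums(acc$samples[, seq_len(n_sec * fs), drop = FALSE]^2))
  dev <- apply(matrix(abs(mag - 1), nrow = fs), 2, max)
  list(t0 = acc$start_time, dev = dev)
}

#' Detect PPG pulses with motion-artifact gating
#'
#' The PPG is band-pass filtered (0.4–4 Hz, 4th-order Butterworth,
#' forward-backward); pulse fiducials are the waveform troughs, i.e. the
#' samples where the first difference crosses zero towards a positive
#' value. Because wrist PPG is unusable during gross motion, the maximum
#' deviation of the raw acceleration magnitude from 1 g is assessed per
#' second, and every fiducial falling in a second exceeding `threshold_g`
#' is discarded.
#'
#' @param ppg a PPG [waveform()] with `fs >= 16` Hz.
#' @param acc the accompanying [triaxial_signal()] on the same clock, or
#'   `NULL` (beats returned ungated, with a warning).
#' @param threshold_g motion gate in g (default 0.1).
#' @return a [beat_series()] on the PPG clock; discarded fiducials keep
#'   `retained = FALSE`.
#' @export
detect_ppg_pulses <- function(ppg, acc, threshold_g = 0.1) {
  if (ppg$kind != "ppg") abort_validation("`ppg` must be a PPG waveform")
  if (ppg$fs < 16) abort_validation("PPG fs must be >= 16 Hz")
  x <- ppg$samples
  if (length(x) < 3 * ppg$fs) abort_validation("PPG too short for pulse detection")
  hi <- min(8, 0.8 * ppg$fs / 2)
  bf <- signal::butter(2, c(0.4, hi) / (ppg$fs / 2), type = "pass")
  f <- filtfilt_pad(bf, x, ppg$fs)
  d <- diff(f)
  trough <- which(d[-length(d)] < 0 & d[-1] > 0) + 1L
  # prominence gate: a pulse trough must be preceded by a diastolic descent
  # and followed by a systolic rise, both a fraction of the robust waveform
  # range (rejects ripple in flat segments); troughs within half a second of
  # the signal edges are unassessable (filter transients) and dropped
  if (length(trough)) {
    rng <- diff(quantile(f, c(0.05, 0.95)))
    look <- max(1L, round(0.3 * ppg$fs))
    n <- length(f)
    rise <- fall <- rep(-Inf, length(trough))
    for (s in 0:look) {        # windowed max via shift reduction
      rise <- pmax(rise, f[pmin(trough + s, n)])
      fall <- pmax(fall, f[pmax(trough - s, 1L)])
    }
    rise <- rise - f[trough]; fall <- fall - f[trough]
    edge <- round(0.5 * ppg$fs)
    trough <- trough[rise >= 0.1 * rng & fall >= 0.08 * rng &
                     trough > edge & trough <= length(f) - edge]
  }
  # merge troughs closer than the shortest plausible interbeat interval,
  # keeping the deeper one (single greedy scan)
  if (length(trough) > 1L) {
    kept <- integer(length(trough)); nk <- 0L
    for (i in trough) {
      if (nk == 0L || (i - kept[nk]) / ppg$fs >= IBI_BAND[1]) {
        nk <- nk + 1L; kept[nk] <- i
      } else if (f[i] < f[kept[nk]]) {
        kept[nk] <- i
      }
    }
    trough <- kept[seq_len(nk)]
  }
  # sub-sample trough localization: parabola through the three samples
  # around the minimum (keeps IBI jitter well below the sample period)
  delta <- rep(0, length(trough))
  inner <- trough > 1L & trough < length(f)
  if (any(inner)) {
    i <- trough[inner]
    den <- f[i - 1L] - 2 * f[i] + f[i + 1L]
    d0 <- ifelse(abs(den) > 1e-12, 0.5 * (f[i - 1L] - f[i + 1L]) / den, 0)
    delta[inner] <- pmax(pmin(d0, 0.5), -0.5)
  }
  times <- ppg$start_time + (trough - 1L + delta) / ppg$fs
  retained <- rep(TRUE, length(times))
  if (is.null(acc)) {
    warning("no accelerometer overlap: PPG beats returned ungated", call. = FALSE)
  } else {
    if (!identical(acc$clock_id, ppg$clock_id))
      abort_validation("PPG and accelerometer must be on the same clock")
    mot <- acc_motion_per_second(acc)
    sec <- floor(times - mot$t0) + 1L
    inside <- sec >= 1L & sec <= length(mot$dev)
    if (!any(inside)) {
      warning("no accelerometer overlap: PPG beats returned ungated", call. = FALSE)
    } else {
      gated <- inside & mot$dev[pmax(pmin(sec, length(mot$dev)), 1L)] > threshold_g
      retained[gated] <- FALSE
    }
  }
  # enforce strictly increasing retained times (duplicate-sample troughs)
  keep <- retained
  rt <- times[keep]
  if (length(rt) > 1L) {
    dup <- c(FALSE, diff(rt) <= 0)
    if (any(dup)) keep[which(keep)[dup]] <- FALSE
  }
  beat_series(times, keep, clock_id = ppg$clock_id)
}

#' Detect QRS complexes in an ECG waveform
#'
#' A Pan–Tompkins-style energy detector: band-pass 5–15 Hz, differentiate,
#' square, moving-window integrate (150 ms), threshold at a fraction of the
#' upper envelope with a 250 ms refractory period, then localize each beat
#' at the raw-signal extremum within +/- 50 ms of the energy peak.
#'
#' @param ecg an ECG [waveform()] (`fs >= 100` Hz recommended).
#' @param refractory minimum beat spacing (s).
#' @return a [beat_series()] on the ECG clock (empty, with a warning, for a
#'   flat signal).
#' @export
detect_qrs <- function(ecg, refractory = 0.25) {
  if (ecg$kind != "ecg") abort_validation("`ecg` must be an ECG waveform")
  fs <- ecg$fs
  x <- ecg$samples
  if (length(x) < fs || sd(x) < 1e-12) {
    warning("flat or empty ECG: no beats detected", call. = FALSE)
    return(beat_series(numeric(0), clock_id = ecg$clock_id))
  }
  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  f <- filtfilt_pad(bf, x, fs)
  energy <- c(0, diff(f))^2
  w <- max(1L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(energy, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- 0.2 * quantile(integ, 0.99)
  above <- integ > thr
  # candidate = local max of the integrated energy inside supra-threshold runs
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L); ends <- which(d == -1L) - 1L
  cand <- mapply(function(s, e) s - 1L + which.max(integ[s:e]), starts, ends)
  cand <- sort(unname(cand))
  # refractory: greedy keep, preferring earlier (already energy-ranked runs)
  keep <- integer(0); last <- -Inf
  for (c0 in cand) {
    if ((c0 - last) / fs >= refractory) { keep <- c(keep, c0); last <- c0 }
  }
  half <- round(0.05 * fs)
  med <- median(x)
  loc <- vapply(keep, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    seg <- abs(x[lo:hi] - med)
    j <- lo - 1L + which.max(seg)
    # parabolic sub-sample refinement of the R-peak instant
    if (j > 1L && j < length(x)) {
      m <- abs(x[(j - 1L):(j + 1L)] - med)
      den <- m[1] - 2 * m[2] + m[3]
      if (abs(den) > 1e-12) j <- j + max(min(0.5 * (m[1] - m[3]) / den, 0.5), -0.5)
    }
    j
  }, 0)
  times <- ecg$start_time + (sort(loc) - 1) / fs
  times <- times[c(TRUE, diff(times) > 0)]
  beat_series(times, clock_id = ecg$clock_id)
}

#' Interbeat intervals from a beat series
#'
#' Interval `i` is `t[i+1] - t[i]` over the retained beats, anchored at the
#' later beat `t[i+1]`. Intervals outside the 0.27–2.0 s plausibility band
#' (including bridges across discarded beats) are flagged invalid.
#'
#' @param bs a [beat_series()] (or a numeric vector of beat times).
#' @return an `"ibi_series"`: `anchor_times`, `intervals`, `valid`,
#'   `clock_id`.
#' @export
beats_to_ibi <- function(bs) {
  if (is.numeric(bs)) bs <- beat_series(bs)
  t <- retained_beats(bs)
  if (length(t) < 2L)
    return(structure(list(anchor_times = numeric(0), intervals = numeric(0),
                          valid = logical(0), clock_id = bs$clock_id),
                     class = "ibi_series"))
  iv <- diff(t)
  structure(list(anchor_times = t[-1], intervals = iv,
                 valid = iv >= IBI_BAND[1] & iv <= IBI_BAND[2],
                 clock_id = bs$clock_id),
            class = "ibi_series")
}

# linear interpolation of the valid (anchor, interval) points on a uniform
# grid; samples in invalid bridges or outside the valid anchor span are NA
interp_ibi <- function(ibi, t_grid) {
  va <- ibi$anchor_times[ibi$valid]
  vi <- ibi$intervals[ibi$valid]
  if (length(va) < 2L) return(rep(NA_real_, length(t_grid)))
  out <- approx(va, vi, xout = t_grid, rule = 1)$y
  bad <- which(!ibi$valid)
  for (i in bad) {
    a <- ibi$anchor_times[i]
    out[t_grid > a - ibi$intervals[i] & t_grid < a] <- NA_real_
  }
  out
}

#' Instantaneous heart rate at 10 Hz
#'
#' The valid interbeat intervals are linearly interpolated onto a uniform
#' 10 Hz grid aligned with the epoch grid, inverted and multiplied by 60 to
#' give bpm. Samples inside invalid gaps, before the first / after the last
#' valid anchor, or in non-rest epochs are set to the 0 sentinel.
#'
#' @param ibi an `ibi_series` on the wearable clock.
#' @param rest_mask logical [epoch_series()] (`TRUE` = resting) on the same
#'   clock, or `NULL` to keep all epochs.
#' @param start_time,n_epochs epoch grid to rasterise onto; default from
#'   `rest_mask`.
#' @return an `"ihr_series"`: `values` (length `300 * n_epochs`), `fs = 10`,
#'   `start_time`, `clock_id`.
#' @export
ibi_to_ihr <- function(ibi, rest_mask = NULL,
                       start_time = rest_mask$start_time,
                       n_epochs = length(rest_mask$values)) {
  if (is.null(start_time) || is.null(n_epochs))
    abort_validation("need rest_mask or explicit start_time/n_epochs")
  n <- as.integer(n_epochs) * EPOCH_SEC * IHR_FS
  t_grid <- start_time + (seq_len(n) - 1L) / IHR_FS
  iv <- interp_ibi(ibi, t_grid)
  ihr <- ifelse(is.na(iv), 0, pmin(60 / iv, 220))
  ihr[ihr < 30 & ihr != 0] <- 0
  if (!is.null(rest_mask)) {
    ep <- pmin(floor((t_grid - start_time) / EPOCH_SEC) + 1L, as.integer(n_epochs))
    ihr[!as.logical(rest_mask$values)[ep]] <- 0
  }
  structure(list(values = ihr, fs = IHR_FS, start_time = start_time,
                 clock_id = ibi$clock_id),
            class = "ihr_series")
}

#' The wearable-vs-PSG clock model
#'
#' Frozen direction convention used everywhere in the package:
#' `wearable_time = psg_time * (1 + drift) + offset`.
#'
#' @param offset clock offset in seconds.
#' @param drift dimensionless skew (|drift| < 1e-3).
#' @param correlation_at_optimum Pearson correlation achieved at the
#'   optimum of the synchronization search.
#' @return a `"clock_model"`.
#' @export
clock_model <- function(offset, drift, correlation_at_optimum = NA_real_) {
  if (abs(drift) >= 1e-3) abort_validation("|drift| must be < 1e-3")
  structure(list(offset = as.numeric(offset), drift = as.numeric(drift),
                 correlation_at_optimum = as.numeric(correlation_at_optimum)),
            class = "clock_model")
}

#' @rdname clock_model
#' @param t_psg times on the PSG clock.
#' @param cm a `clock_model`.
#' @export
psg_to_wearable <- function(t_psg, cm) t_psg * (1 + cm$drift) + cm$offset

#' @rdname clock_model
#' @param t_wear times on the wearable clock.
#' @export
wearable_to_psg <- function(t_wear, cm) (t_wear - cm$offset) / (1 + cm$drift)

# classic ectopic/missed-beat rejection: intervals far from the local
# running median (missed beat -> ~2x, spurious beat -> ~0.5x) are invalidated
clean_ibi <- function(ibi, lo = 0.7, hi = 1.4) {
  v <- ibi$intervals
  if (length(v) >= 5) {
    rm5 <- stats::runmed(v, 5, endrule = "median")
    ibi$valid <- ibi$valid & v >= lo * rm5 & v <= hi * rm5
  }
  ibi
}

resample_ibi_uniform <- function(ibi, fs = 4) {
  va <- ibi$anchor_times[ibi$valid]
  if (length(va) < 2L) abort_validation("too few valid intervals to synchronize")
  t0 <- va[1]; t1 <- va[length(va)]
  t_grid <- seq(t0, t1, by = 1 / fs)
  list(t = t_grid, v = interp_ibi(ibi, t_grid))
}

#' Synchronize the wearable clock to the PSG clock
#'
#' Finds the offset and drift maximising the Pearson correlation between
#' the ECG-derived IBI series (PSG clock) and the PPG-derived IBI series
#' (wearable clock), both resampled to a common uniform 4 Hz grid. The
#' search is an exhaustive coarse grid (offsets +/-120 s in 0.25 s steps via
#' FFT cross-correlation, drifts +/-2e-4 in 1e-5 steps) followed by a local
#' refinement at 10x finer steps with exact correlation on the overlapping
#' valid samples.
#'
#' @param ibi_ecg `ibi_series` on the PSG clock.
#' @param ibi_ppg `ibi_series` on the wearable clock.
#' @param offset_range,offset_step,drift_range,drift_step search grids
#'   (s and dimensionless).
#' @param min_overlap_s minimum overlap of valid samples (default 600 s).
#' @param min_corr minimum acceptable correlation at the optimum.
#' @return a [clock_model()]; on failure a condition of class
#'   `"wearstage_sync_error"` carrying the best candidate is signalled.
#' @export
synchronize_clocks <- function(ibi_ecg, ibi_ppg,
                               offset_range = c(-120, 120), offset_step = 0.25,
                               drift_range = c(-2e-4, 2e-4), drift_step = 1e-5,
                               min_overlap_s = 600, min_corr = 0.5) {
  fs <- 1 / offset_step
  ibi_ecg <- clean_ibi(ibi_ecg)
  ibi_ppg <- clean_ibi(ibi_ppg)
  e <- resample_ibi_uniform(ibi_ecg, fs)
  ev <- e$v; ev_ok <- !is.na(ev)
  if (sum(ev_ok) < min_overlap_s * fs)
    abort_validation("less than the minimum overlap of valid ECG intervals")
  e0 <- ifelse(ev_ok, ev - mean(ev[ev_ok]), 0)
  drifts <- seq(drift_range[1], drift_range[2], by = drift_step)
  wa <- ibi_ppg$anchor_times[ibi_ppg$valid]
  if (length(wa) < 2L) abort_validation("too few valid PPG intervals to synchronize")
  nfft <- 2^ceiling(log2(length(e0) + 2 * (diff(offset_range) * fs + 4)))
  fe <- fft(c(e0, rep(0, nfft - length(e0))))
  max_lag <- ceiling(offset_range[2] * fs)
  best <- list(score = -Inf, offset = 0, drift = 0)
  for (d in drifts) {
    # PPG interval value at psg time tau is p(tau (1+d) + o); on the ECG grid
    # an offset o is a shift of o*fs samples of the drift-warped resample
    pv <- interp_ibi(ibi_ppg, e$t * (1 + d))
    pok <- !is.na(pv)
    if (!any(pok)) next
    p0 <- ifelse(pok, pv - mean(pv[pok]), 0)
    fp <- fft(c(p0, rep(0, nfft - length(p0))))
    cc <- Re(fft(fe * Conj(fp), inverse = TRUE)) / nfft
    # cc index m corresponds to sum_j e0[j] q0[j - m], i.e. offset o = -m/fs;
    # the tail indices (circular m = -k) carry the positive offsets
    lags <- -c(0:max_lag, if (max_lag >= 1) -(max_lag:1))
    vals <- cc[c(1:(max_lag + 1), if (max_lag >= 1) (nfft - max_lag + 1):nfft)]
    sc <- vals / (sd(e0) * sd(p0) * length(e0))
    i <- which.max(sc)
    if (sc[i] > best$score)
      best <- list(score = sc[i], offset = lags[i] / fs, drift = d)
  }
  # refinement with exact Pearson on overlapping valid samples. The coarse
  # correlation surface has a ridge along offset ~ offset* + tau_c (drift* -
  # drift) (a drift error is compensated at the overlap centre tau_c by an
  # offset shift), so drift is profiled over its full range along that
  # ridge before a final local polish at 10x finer steps.
  exact_corr <- function(o, d) {
    pv <- interp_ibi(ibi_ppg, e$t * (1 + d) + o)
    ok <- ev_ok & !is.na(pv)
    if (sum(ok) < min_overlap_s * fs) return(NA_real_)
    suppressWarnings(cor(ev[ok], pv[ok]))
  }
  tau_c <- mean(e$t)
  ref <- list(corr = -Inf, offset = best$offset, drift = best$drift)
  scan <- function(drifts, off_centre_of, off_span, off_step) {
    for (d in drifts) {
      for (o in off_centre_of(d) + seq(-off_span, off_span, by = off_step)) {
        r <- exact_corr(o, d)
        if (!is.na(r) && r > ref$corr) ref <<- list(corr = r, offset = o, drift = d)
      }
    }
  }
  # drift profile over the full range along the ridge; offsets must be
  # sampled finely or ridge-compensation error drowns the drift signal
  scan(seq(drift_range[1], drift_range[2], by = drift_step / 2),
       function(d) best$offset + tau_c * (best$drift - d),
       offset_step, offset_step / 10)
  # local polish at 10x finer steps around the profile argmax
  scan(ref$drift + seq(-drift_step, drift_step, by = drift_step / 10),
       local({ oc <- ref$offset; dc <- ref$drift
               function(d) oc + tau_c * (dc - d) }),
       offset_step / 5, offset_step / 50)
  if (!is.finite(ref$corr) || ref$corr < min_corr)
    abort_ws(sprintf("clock synchronization failed (best correlation %.3f)",
                     if (is.finite(ref$corr)) ref$corr else NA),
             "wearstage_sync_error",
             best = clock_model(ref$offset, ref$drift, ref$corr))
  clock_model(ref$offset, ref$drift, ref$corr)
}
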