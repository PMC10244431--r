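test_that("activity counts vanish for gravity-only and all-zero signals", {
  fs <- 16
  for (g in list(c(0, 0, 1), c(0.3, 0.4, sqrt(1 - 0.25)), c(1, 0, 0))) {
    acc <- triaxial_signal(matrix(rep(g, 90 * fs), nrow = 3), fs = fs)
    expect_equal(sum(compute_activity_counts(acc)$values), 0)
  }
  acc0 <- triaxial_signal(matrix(0, 3, 60 * fs), fs = fs)
  expect_equal(sum(compute_activity_counts(acc0)$values), 0)
})

test_that("activity counts match a straight-line reimplementation of the recipe", {
  # independent oracle: loop over axes / seconds / samples, literally
  # following gravity-estimate subtraction with clamping at zero
  oracle_counts <- function(samples, fs) {
    bf <- signal::butter(3, 1 / (fs / 2), type = "low")
    n_sec <- ncol(samples) %/% fs
    sec <- numeric(n_sec)
    for (ax in 1:3) {
      f <- wearstage:::filtfilt_pad(bf, samples[ax, ], fs)  # shared filter; the
      # aggregation below is the independent reimplementation
      for (s in seq_len(n_sec)) {
        w <- abs(f[(s - 1) * fs + seq_len(fs)])
        grav <- mean(w)
        for (v in w) sec[s] <- sec[s] + max(v - grav, 0)
      }
    }
    ep <- numeric(n_sec %/% 30)
    for (e in seq_along(ep)) ep[e] <- sum(sec[(e - 1) * 30 + 1:30])
    ep
  }
  set.seed(9)
  fs <- 8
  x <- matrix(rep(c(0, 0, 1), 60 * fs), nrow = 3)
  x[1, 200 + 1:10] <- x[1, 200 + 1:10] + 0.7          # square burst, known size
  x[2, ] <- x[2, ] + rnorm(ncol(x), 0, 0.05)
  acc <- triaxial_signal(x, fs = fs)
  expect_equal(as.numeric(compute_activity_counts(acc)$values),
               oracle_counts(x, fs), tolerance = 1e-10)
})

test_that("activity counts are nearly invariant to device orientation", {
  # invariance holds when each axis keeps a gravity component larger than
  # the burst amplitude (the per-axis absolute value never folds); a
  # gravity vector along one axis is the degenerate exception
  set.seed(10)
  fs <- 16
  g <- c(0.55, 0.6, sqrt(1 - 0.55^2 - 0.6^2))
  base <- matrix(rep(g, 120 * fs), nrow = 3)
  idx <- 500 + seq_len(4 * fs)
  burst <- matrix(0, 3, ncol(base))
  osc <- sin(2 * pi * 0.7 * seq_len(4 * fs) / fs)   # inside the 1 Hz band
  burst[, idx] <- outer(c(0.25, -0.2, 0.15), osc)
  x <- base + burst
  th <- 0.2   # a realistic wear-angle change; the recipe's per-axis L1
  # aggregation is not exactly rotation invariant for large re-orientations
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
       rbind(c(1, 0, 0), c(0, cos(0.15), -sin(0.15)), c(0, sin(0.15), cos(0.15)))
  c1 <- sum(compute_activity_counts(triaxial_signal(x, fs = fs))$values)
  c2 <- sum(compute_activity_counts(triaxial_signal(R %*% x, fs = fs))$values)
  expect_lt(abs(c1 - c2) / c1, 0.05)
})

test_that("a 1 Hz sinusoid yields one PPG trough per second", {
  fs <- 32
  t <- (0:(60 * fs - 1)) / fs
  ppg <- waveform(sin(2 * pi * t), fs = fs, kind = "ppg")
  acc <- triaxial_signal(matrix(rep(c(0, 0, 1), length(t)), nrow = 3), fs = fs)
  bs <- detect_ppg_pulses(ppg, acc)
  rb <- retained_beats(bs)
  expect_equal(length(rb), 59, tolerance = 0.04)  # edges excluded
  expect_lt(max(abs(diff(rb) - 1)), 2 / fs)
})

test_that("pulse detection on a clean synthetic night is near-perfect and honours the motion gate", {
  sr <- clean_night()
  bs <- detect_ppg_pulses(sr$recording$ppg, sr$recording$acc)
  rb <- retained_beats(bs)
  tw <- sr$true_beats_wearable
  tol <- 1 / sr$recording$ppg$fs + 1e-9
  err <- vapply(rb, function(z) min(abs(tw - z)), 0)
  matched <- vapply(tw[tw > 1 & tw < max(tw) - 1],
                    function(z) min(abs(rb - z)), 0)
  expect_gt(mean(err <= tol), 0.99)       # precision
  expect_gt(mean(matched <= tol), 0.99)   # recall

  # gating: zero retained beats inside > 0.1 g seconds (hard assertion)
  srb <- small_night()
  bsb <- detect_ppg_pulses(srb$recording$ppg, srb$recording$acc)
  mot <- wearstage:::acc_motion_per_second(srb$recording$acc)
  sec <- floor(retained_beats(bsb) - mot$t0) + 1L
  expect_equal(sum(mot$dev[sec] > 0.1), 0)
  expect_gt(sum(!bsb$retained), 0)  # some fiducials were really discarded

  # without accelerometer the beats come back ungated, with a warning
  expect_warning(ung <- detect_ppg_pulses(srb$recording$ppg, NULL),
                 regexp = "ungated")
  expect_true(all(ung$retained))
})

test_that("QRS detection localizes beats and rejects flat signals", {
  sr <- clean_cfg()
  rec <- simulate_recording(sr)
  qb <- retained_beats(detect_qrs(rec$recording$ecg))
  err <- vapply(qb, function(z) min(abs(rec$true_beats - z)), 0)
  expect_gt(mean(err <= 0.010), 0.99)
  expect_equal(length(qb), length(rec$true_beats), tolerance = 0.01)

  # constant 70 bpm: IBI constant at 60/70 s
  cfg70 <- flat_cfg(70)
  hyp <- hypnogram(rep("N3", 10))
  beats <- simulate_beats(cfg70, hyp)
  ecg <- suppressWarnings(render_ecg(cfg70, beats, duration = 300))
  ibi <- beats_to_ibi(detect_qrs(ecg))
  expect_lt(max(abs(ibi$intervals - 60 / 70)), 1 / cfg70$ecg_fs + 1e-9)

  flat <- waveform(rep(0.5, 1000), fs = 128, kind = "ecg")
  expect_warning(empty <- detect_qrs(flat), regexp = "flat")
  expect_length(retained_beats(empty), 0)
})

test_that("interbeat intervals anchor at the later beat and flag implausible gaps", {
  ibi <- beats_to_ibi(c(0, 1, 2.5))
  expect_equal(ibi$intervals, c(1.0, 1.5))
  expect_equal(ibi$anchor_times, c(1, 2.5))
  expect_true(all(ibi$valid))

  # a discarded middle beat produces an invalid bridging interval
  bs <- beat_series(c(0, 1, 2.2, 3.2), retained = c(TRUE, TRUE, FALSE, TRUE))
  ibi2 <- beats_to_ibi(bs)
  expect_equal(ibi2$intervals, c(1, 2.2))
  expect_identical(ibi2$valid, c(TRUE, FALSE))

  # inverse operation: cumulative sum of intervals reproduces beat times
  set.seed(2)
  t <- cumsum(runif(50, 0.6, 1.2))
  ibi3 <- beats_to_ibi(t)
  expect_equal(t[1] + cumsum(ibi3$intervals), t[-1], tolerance = 1e-12)

  expect_length(beats_to_ibi(c(1))$intervals, 0)
})

test_that("IHR resampling inverts intervals at 10 Hz with sentinel zeros", {
  mk_ibi <- function(anchors, ivals)
    structure(list(anchor_times = anchors, intervals = ivals,
                   valid = rep(TRUE, length(ivals)), clock_id = "wearable"),
              class = "ibi_series")
  # constant 1 s intervals -> exactly 60 bpm inside the anchor span
  ibi <- beats_to_ibi(0:60)
  ihr <- ibi_to_ihr(ibi, start_time = 0, n_epochs = 2)
  inside <- ihr$values[ (ihr$values > 0) ]
  expect_true(all(abs(inside - 60) < 1e-9))
  expect_equal(ihr$fs, 10)
  expect_length(ihr$values, 2 * 300)

  ihr2 <- ibi_to_ihr(beats_to_ibi(seq(0, 60, by = 0.5)), start_time = 0, n_epochs = 2)
  expect_true(all(abs(ihr2$values[ihr2$values > 0] - 120) < 1e-9))

  # hand-computed linear interpolation: anchors (10 s, 1.0 s), (11 s, 0.8 s)
  ibi3 <- mk_ibi(c(10, 11), c(1.0, 0.8))
  ihr3 <- ibi_to_ihr(ibi3, start_time = 0, n_epochs = 1)
  at <- function(t) ihr3$values[round(t * 10) + 1]
  expect_equal(at(10.5), 60 / 0.9, tolerance = 1e-9)
  expect_equal(at(9.0), 0)    # before the first valid anchor
  expect_equal(at(12.0), 0)   # after the last

  # rest mask zeroes whole epochs, leaves others strictly positive
  ibi4 <- beats_to_ibi(0:120)
  mask <- epoch_series(c(TRUE, FALSE, TRUE, TRUE), start_time = 0)
  ihr4 <- ibi_to_ihr(ibi4, rest_mask = mask)
  ep_of <- rep(1:4, each = 300)
  expect_true(all(ihr4$values[ep_of == 2] == 0))
  expect_true(all(ihr4$values[ep_of == 3] > 0))
})

test_that("clock synchronization: self-sync, parameter recovery, rejection", {
  sr <- cached("sync_night", simulate_recording(
    synth_config(n_epochs = 70, pre_bed_active_minutes = 2,
                 post_bed_active_minutes = 1, clock_offset = -7.25,
                 clock_drift = -4e-5, seed = 33)))
  ibi_e <- beats_to_ibi(detect_qrs(sr$recording$ecg))
  ibi_p <- beats_to_ibi(detect_ppg_pulses(sr$recording$ppg, sr$recording$acc))

  # identical series: the optimum is (0, 0, corr 1) up to the resolution of
  # the refinement grid (the surface is numerically tied near the optimum)
  self <- synchronize_clocks(ibi_e, ibi_e)
  expect_lt(abs(self$offset), 0.025 + 1e-9)
  expect_lt(abs(self$drift), 1e-5)
  expect_gt(self$correlation_at_optimum, 0.9999)

  cm <- synchronize_clocks(ibi_e, ibi_p)
  expect_lt(abs(cm$offset - (-7.25)), 0.25)
  expect_lt(abs(cm$drift - (-4e-5)), 1e-5)
  expect_gt(cm$correlation_at_optimum, 0.9)

  # uncorrelated random interval series must be rejected
  set.seed(4)
  r1 <- beats_to_ibi(cumsum(runif(1200, 0.7, 1.1)))
  r2 <- beats_to_ibi(cumsum(runif(1200, 0.7, 1.1)))
  err <- tryCatch(synchronize_clocks(r1, r2), condition = identity)
  expect_s3_class(err, "wearstage_sync_error")
  expect_s3_class(err$best, "clock_model")
  expect_error(synchronize_clocks(beats_to_ibi(c(0, 1)), ibi_p),
               class = "wearstage_validation_error")
})

test_that("synchronization error does not grow with overlap duration", {
  sr <- cached("sync_night2", simulate_recording(
    synth_config(n_epochs = 130, pre_bed_active_minutes = 0,
                 post_bed_active_minutes = 0, clock_offset = 3.8,
                 clock_drift = 6e-5, seed = 44)))
  ibi_e <- beats_to_ibi(detect_qrs(sr$recording$ecg))
  ibi_p <- beats_to_ibi(detect_ppg_pulses(sr$recording$ppg, sr$recording$acc))
  trunc_ibi <- function(ibi, t_max) {
    keep <- ibi$anchor_times <= t_max
    ibi$anchor_times <- ibi$anchor_times[keep]
    ibi$intervals <- ibi$intervals[keep]
    ibi$valid <- ibi$valid[keep]
    ibi
  }
  err_at <- function(minutes) {
    cm <- synchronize_clocks(trunc_ibi(ibi_e, minutes * 60),
                             trunc_ibi(ibi_p, minutes * 60 * (1 + 6e-5) + 3.8))
    abs(cm$offset - 3.8) + minutes * 60 * abs(cm$drift - 6e-5)
  }
  errs <- c(err_at(15), err_at(30), err_at(60))
  # allow tiny non-monotonicity at the sub-sample level
  expect_lte(errs[2], errs[1] + 0.05)
  expect_lte(errs[3], errs[2] + 0.05)
  expect_lt(errs[3], 0.25)
})
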