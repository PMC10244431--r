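#' Synthetic night configuration
#'
#' Parameters of the synthetic-recording generator. Defaults describe a
#' plausible 8-h clinical night whose stage-dependent structure matches the
#' assumptions of the staging pipeline: a first-order Markov hypnogram whose
#' stationary distribution equals the pooled stage prevalences of a large
#' wearable validation cohort (17.7 / 50.6 / 16.8 / 15.0% for Wake, N1-N2,
#' N3, REM), stage-dependent mean heart rate with respiratory sinus
#' arrhythmia (strongest in N3) and a low-frequency oscillation (strongest
#' in Wake/REM), stage-dependent movement-burst rates (Wake >> REM > N1-N2 >
#' N3), walking segments before and after the in-bed period, and a wearable
#' clock with configurable offset and drift relative to the PSG clock.
#' These autonomic defaults are configuration for testability, not claims
#' about any cohort's physiology.
#'
#' @param n_epochs number of 30-s epochs in the night.
#' @param transition_matrix 4 x 4 row-stochastic epoch-to-epoch transition
#'   matrix in the order Wake, N1-N2, N3, REM.
#' @param stage_hr_mean,stage_hr_sd per-stage mean heart rate and white
#'   rate jitter (bpm).
#' @param rsa_amp per-stage respiratory sinus arrhythmia amplitude (bpm) at
#'   `resp_freq` (Hz).
#' @param lf_amp per-stage low-frequency oscillation amplitude (bpm) at
#'   `lf_freq` (Hz).
#' @param movement_rate per-stage expected movement bursts per epoch.
#' @param burst_amp,burst_dur movement burst amplitude (g) and duration (s).
#' @param artifact_noise_sd amplitude of the replacement noise that
#'   overwrites the PPG during movement bursts (waveform units; the clean
#'   pulse has unit amplitude).
#' @param pre_bed_active_minutes,post_bed_active_minutes walking segments
#'   before/after the in-bed period (min).
#' @param clock_offset,clock_drift wearable clock model:
#'   `wearable_time = psg_time * (1 + drift) + offset`.
#' @param ppg_fs,ecg_fs,acc_fs rendering sample rates (Hz).
#' @param ppg_noise_sd additive Gaussian sensor noise on the clean PPG
#'   (waveform units).
#' @param ppg_wander_amp amplitude of the slow (0.05 Hz) PPG baseline
#'   wander (waveform units).
#' @param posture_change_prob per-epoch probability of a posture change
#'   (re-orientation of the gravity vector).
#' @param resp_freq,lf_freq modulation frequencies (Hz).
#' @param seed integer seed; the whole night is a deterministic function of
#'   the configuration.
#' @return a `"synth_config"` list.
#' @export
synth_config <- function(n_epochs = 960,
                         transition_matrix = default_transition_matrix(),
                         stage_hr_mean = c(WAKE = 70, N1N2 = 62, N3 = 58, REM = 66),
                         stage_hr_sd = c(WAKE = 2, N1N2 = 1.5, N3 = 1, REM = 2),
                         rsa_amp = c(WAKE = 1, N1N2 = 2, N3 = 3, REM = 1.5),
                         resp_freq = 0.25,
                         lf_amp = c(WAKE = 3, N1N2 = 1, N3 = 0.5, REM = 3),
                         lf_freq = 0.095,
                         movement_rate = c(WAKE = 0.6, N1N2 = 0.05, N3 = 0.01, REM = 0.1),
                         burst_amp = 0.5, burst_dur = 1.5,
                         artifact_noise_sd = 2,
                         pre_bed_active_minutes = 30,
                         post_bed_active_minutes = 10,
                         clock_offset = 0, clock_drift = 0,
                         ppg_fs = 32, ecg_fs = 128, acc_fs = 16,
                         ppg_noise_sd = 0.02, ppg_wander_amp = 0.1,
                         posture_change_prob = 0.02,
                         seed = 1L) {
  cfg <- list(n_epochs = as.integer(n_epochs), transition_matrix = transition_matrix,
              stage_hr_mean = stage_hr_mean, stage_hr_sd = stage_hr_sd,
              rsa_amp = rsa_amp, resp_freq = resp_freq, lf_amp = lf_amp,
              lf_freq = lf_freq, movement_rate = movement_rate,
              burst_amp = burst_amp, burst_dur = burst_dur,
              artifact_noise_sd = artifact_noise_sd,
              pre_bed_active_minutes = pre_bed_active_minutes,
              post_bed_active_minutes = post_bed_active_minutes,
              clock_offset = clock_offset, clock_drift = clock_drift,
              ppg_fs = ppg_fs, ecg_fs = ecg_fs, acc_fs = acc_fs,
              ppg_noise_sd = ppg_noise_sd, ppg_wander_amp = ppg_wander_amp,
              posture_change_prob = posture_change_prob,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  P <- cfg$transition_matrix
  if (!is.matrix(P) || any(dim(P) != 4L) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-12))
    abort_validation("transition_matrix must be 4 x 4 row-stochastic (rows sum to 1)")
  for (nm in c("stage_hr_mean", "stage_hr_sd", "rsa_amp", "lf_amp", "movement_rate")) {
    v <- cfg[[nm]]
    if (length(v) != 4L || any(!is.finite(v)) || any(v < 0))
      abort_validation(sprintf("`%s` must be 4 non-negative per-stage values", nm))
  }
  if (any(cfg$stage_hr_mean <= 0)) abort_validation("stage_hr_mean must be > 0")
  if (cfg$n_epochs < 0) abort_validation("n_epochs must be >= 0")
  if (abs(cfg$clock_drift) >= 1e-3) abort_validation("|clock_drift| must be < 1e-3")
  invisible(cfg)
}

#' @rdname synth_config
#' @param persistence per-epoch probability of keeping the current stage
#'   dynamics (the complement redraws from the stationary distribution).
#' @param stationary stationary stage probabilities (Wake, N1-N2, N3, REM);
#'   the default is the pooled-prevalence vector, renormalised.
#' @export
default_transition_matrix <- function(persistence = 0.88,
                                      stationary = c(0.177, 0.506, 0.168, 0.150)) {
  pi0 <- stationary / sum(stationary)
  # (1-s) I + s 1 pi' has stationary distribution pi for any s in (0, 1]
  P <- persistence * diag(4) + (1 - persistence) * matrix(pi0, 4, 4, byrow = TRUE)
  dimnames(P) <- list(STAGES, STAGES)
  P
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector of `P` for eigenvalue 1, normalised to sum to 1.
#'
#' @param P row-stochastic square matrix.
#' @return numeric stationary probability vector.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

maybe_seed <- function(seed) if (!is.null(seed)) set.seed(seed)

n_pre_epochs <- function(cfg) as.integer(ceiling(cfg$pre_bed_active_minutes * 60 / EPOCH_SEC))
n_post_epochs <- function(cfg) as.integer(ceiling(cfg$post_bed_active_minutes * 60 / EPOCH_SEC))

#' Simulate a stage-labelled hypnogram
#'
#' Pre- and post-bed walking margins are forced Wake; the in-bed portion is
#' a first-order Markov chain over Wake, N1-N2, N3, REM starting in Wake.
#' The lights-off interval spans the in-bed portion.
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed, or `NULL` to continue from the current RNG
#'   state (used when composing generators).
#' @return a [hypnogram()] on the `"psg"` clock.
#' @export
simulate_hypnogram <- function(cfg, seed = cfg$seed) {
  validate_synth_config(cfg)
  maybe_seed(seed)
  E <- cfg$n_epochs
  n_pre <- min(n_pre_epochs(cfg), E); n_post <- min(n_post_epochs(cfg), max(0L, E - n_pre))
  n_bed <- E - n_pre - n_post
  states <- integer(0)
  if (n_bed > 0) {
    states <- integer(n_bed); states[1] <- 1L  # first in-bed epoch is Wake
    P <- cfg$transition_matrix
    for (i in seq_len(n_bed - 1L))
      states[i + 1L] <- sample.int(4L, 1L, prob = P[states[i], ])
  }
  labels <- c(rep("WAKE", n_pre), STAGES[states], rep("WAKE", n_post))
  lo <- if (n_bed > 0) EPOCH_SEC * c(n_pre, n_pre + n_bed) else NULL
  hypnogram(labels, start_time = 0, clock_id = "psg", lights_off = lo)
}

stage_idx_per_epoch <- function(hyp) {
  i <- as.integer(stage_factor(hyp$values))
  i[i > 4L] <- 1L  # UNSCORED carries Wake-like dynamics
  i
}

#' Simulate heart-beat instants by integral pulse frequency modulation
#'
#' The instantaneous rate is `r(t) = stage mean + RSA sine + LF sine +
#' white jitter` (all per configuration), clamped to 30–180 bpm; a beat is
#' emitted each time the running integral of `r(t)/60` crosses the next
#' integer. Beat times are on the PSG/reference clock.
#'
#' @param hyp a [hypnogram()] defining the stage sequence.
#' @inheritParams simulate_hypnogram
#' @return numeric vector of beat times (s).
#' @export
simulate_beats <- function(cfg, hyp, seed = cfg$seed) {
  if (n_epochs(hyp) == 0L) abort_validation("hypnogram is empty")
  maybe_seed(seed)
  dt <- 0.125
  dur <- EPOCH_SEC * n_epochs(hyp)
  t <- seq(0, dur - dt, by = dt)
  sidx <- stage_idx_per_epoch(hyp)[pmin(floor(t / EPOCH_SEC) + 1L, n_epochs(hyp))]
  ph_r <- runif(1, 0, 2 * pi); ph_l <- runif(1, 0, 2 * pi)
  r <- cfg$stage_hr_mean[sidx] +
    cfg$rsa_amp[sidx] * sin(2 * pi * cfg$resp_freq * t + ph_r) +
    cfg$lf_amp[sidx] * sin(2 * pi * cfg$lf_freq * t + ph_l) +
    rnorm(length(t), 0, cfg$stage_hr_sd[sidx])
  r <- pmin(pmax(r, 30), 180)
  cum <- cumsum(r / 60 * dt)
  n_beats <- floor(cum[length(cum)])
  if (n_beats < 1) return(numeric(0))
  # invert the (strictly increasing) integrated rate at integer crossings
  approx(x = c(0, cum), y = c(0, t + dt), xout = seq_len(n_beats))$y
}

## Movement bursts shared by the accelerometer and PPG renderers ------------

sample_bursts <- function(cfg, hyp, seed = NULL) {
  maybe_seed(seed)
  E <- n_epochs(hyp)
  sidx <- stage_idx_per_epoch(hyp)
  rest <- true_rest_epochs(cfg, E)
  counts <- rpois(E, cfg$movement_rate[sidx])
  counts[!rest] <- 0L  # walking segments are modelled separately
  ep <- rep.int(seq_len(E) - 1L, counts)
  if (!length(ep)) return(data.frame(start = numeric(0), end = numeric(0)))
  start <- EPOCH_SEC * ep + runif(length(ep), 0, EPOCH_SEC - cfg$burst_dur)
  b <- data.frame(start = sort(start))
  b$end <- b$start + cfg$burst_dur
  b
}

true_rest_epochs <- function(cfg, E) {
  n_pre <- min(n_pre_epochs(cfg), E); n_post <- min(n_post_epochs(cfg), max(0L, E - n_pre))
  rest <- rep(TRUE, E)
  if (n_pre > 0) rest[seq_len(n_pre)] <- FALSE
  if (n_post > 0) rest[E - seq_len(n_post) + 1L] <- FALSE
  rest
}

in_interval_mask <- function(t, intervals) {
  m <- rep(FALSE, length(t))
  for (i in seq_len(nrow(intervals)))
    m[t >= intervals$start[i] & t < intervals$end[i]] <- TRUE
  m
}

# physical (PSG) time of wearable samples k = 0, 1, ... at rate fs; the
# wearable stamps them offset + k/fs, i.e. psg time (k/fs - 0)/(1 + drift)
wearable_sample_times <- function(cfg, duration, fs) {
  n <- floor(duration * fs * (1 + cfg$clock_drift))
  (seq_len(n) - 1L) / fs / (1 + cfg$clock_drift)
}

#' Render the PPG and ECG waveforms for a simulated beat train
#'
#' The PPG is a periodic pulse template with its trough exactly at each beat
#' time (fast rise over the first 30% of the beat-to-beat interval), plus
#' slow baseline wander and small Gaussian noise; inside movement bursts the
#' waveform is replaced by high-amplitude noise so that pulse detection must
#' fail there. The ECG is a narrow biphasic spike at each beat. The PPG is
#' rendered on the wearable clock (`wearable = psg (1 + drift) + offset`),
#' the ECG on the PSG clock.
#'
#' @param beats beat times (s, PSG clock), sorted.
#' @param duration recording duration (s, PSG clock).
#' @param bursts optional `data.frame(start, end)` of movement bursts
#'   (s, PSG clock) during which the PPG is overwritten by artifact noise.
#' @inheritParams simulate_hypnogram
#' @return a [waveform()].
#' @export
render_ppg <- function(cfg, beats, duration, bursts = NULL, seed = cfg$seed) {
  if (is.unsorted(beats)) abort_validation("beat times must be sorted")
  maybe_seed(seed)
  tau <- wearable_sample_times(cfg, duration, cfg$ppg_fs)
  # identical fixed-width pulse template added at every beat: a symmetric
  # trough exactly at the beat time followed by a fast rise to a systolic
  # bump. A fixed shape (rather than a phase-warped one) keeps the trough
  # geometry independent of the local interbeat interval, so detector
  # localization carries no rate-dependent bias.
  x <- numeric(length(tau))
  fs_t <- cfg$ppg_fs * (1 + cfg$clock_drift)   # samples per psg second
  hump <- function(u) ifelse(abs(u) < 1, cos(pi * u / 2)^2, 0)
  k0 <- floor(-0.15 * fs_t) - 1L; k1 <- ceiling(0.45 * fs_t) + 1L
  base <- floor(beats * fs_t) + 1L
  for (k in k0:k1) {
    idx <- base + k
    okk <- idx >= 1L & idx <= length(tau)
    tt <- tau[idx[okk]] - beats[okk]
    x[idx[okk]] <- x[idx[okk]] - 1.1 * hump(tt / 0.12) +
      0.9 * hump((tt - 0.22) / 0.18)
  }
  x <- x + cfg$ppg_wander_amp * sin(2 * pi * 0.05 * tau) +
    rnorm(length(x), 0, cfg$ppg_noise_sd)
  if (!is.null(bursts) && nrow(bursts)) {
    m <- in_interval_mask(tau, bursts)
    x[m] <- rnorm(sum(m), 0, cfg$artifact_noise_sd)
  }
  waveform(x, fs = cfg$ppg_fs, kind = "ppg",
           start_time = cfg$clock_offset, clock_id = "wearable")
}

#' @rdname render_ppg
#' @export
render_ecg <- function(cfg, beats, duration, seed = cfg$seed) {
  if (is.unsorted(beats)) abort_validation("beat times must be sorted")
  maybe_seed(seed)
  fs <- cfg$ecg_fs
  n <- floor(duration * fs)
  x <- rnorm(n, 0, 0.01) + 0.05 * sin(2 * pi * 0.3 * (seq_len(n) - 1) / fs)
  inside <- beats[beats >= 0.1 & beats <= duration - 0.1]
  if (length(inside) < length(beats))
    warning("beats outside the recording span were clipped", call. = FALSE)
  if (length(inside)) {
    # biphasic QRS-like template: R peak at the beat instant, S dip after
    half <- round(0.06 * fs)
    k <- -half:half
    for (shift in k) {
      idx <- round(inside * fs) + 1L + shift
      ok <- idx >= 1L & idx <= n
      tt <- shift / fs
      x[idx[ok]] <- x[idx[ok]] + exp(-tt^2 / (2 * 0.008^2)) -
        0.35 * exp(-(tt - 0.035)^2 / (2 * 0.012^2)) -
        0.15 * exp(-(tt + 0.035)^2 / (2 * 0.012^2))
    }
  }
  waveform(x, fs = fs, kind = "ecg", start_time = 0, clock_id = "psg")
}

#' Render the triaxial accelerometer signal
#'
#' A unit gravity vector with occasional posture changes, stage-dependent
#' movement bursts (enveloped band-limited oscillation of amplitude
#' `burst_amp`), sensor noise, and sustained rhythmic ~2 Hz walking
#' acceleration during the pre/post-bed active segments. Returned together
#' with the true per-epoch rest mask (everything outside the walking
#' segments).
#'
#' @inheritParams render_ppg
#' @param hyp the simulated [hypnogram()].
#' @return list with `acc` ([triaxial_signal()] on the wearable clock),
#'   `rest_mask` (logical [epoch_series()]), and `bursts` (data frame, PSG
#'   seconds).
#' @export
render_accelerometer <- function(cfg, hyp, bursts = NULL, seed = cfg$seed) {
  maybe_seed(seed)
  E <- n_epochs(hyp)
  dur <- EPOCH_SEC * E
  if (is.null(bursts)) bursts <- sample_bursts(cfg, hyp, seed = NULL)
  tau <- wearable_sample_times(cfg, dur, cfg$acc_fs)
  n <- length(tau)
  ep <- pmin(floor(tau / EPOCH_SEC) + 1L, E)
  # piecewise-constant gravity orientation with per-epoch change probability
  g <- matrix(0, 3, E)
  v <- c(0, 0, 1)
  for (e in seq_len(E)) {
    if (e > 1L && runif(1) < cfg$posture_change_prob) {
      v <- rnorm(3); v <- v / sqrt(sum(v^2))
    }
    g[, e] <- v
  }
  x <- g[, ep, drop = FALSE] + matrix(rnorm(3 * n, 0, 0.01), 3, n)
  rest <- true_rest_epochs(cfg, E)
  active <- !rest[ep]
  if (any(active)) {
    ta <- tau[active]
    walk <- rbind(0.30 * sin(2 * pi * 2 * ta),
                  0.18 * sin(2 * pi * 2 * ta + pi / 3) + 0.08 * sin(2 * pi * 4 * ta),
                  0.22 * sin(2 * pi * 2 * ta + pi / 2))
    x[, active] <- x[, active] + walk
  }
  for (i in seq_len(nrow(bursts))) {
    m <- which(tau >= bursts$start[i] & tau < bursts$end[i])
    if (!length(m)) next
    env <- sin(pi * (tau[m] - bursts$start[i]) / (bursts$end[i] - bursts$start[i]))
    # a gravity-aligned component plus a transverse one: wrist movements tilt
    # the sensor, so the magnitude deviation reliably reflects burst_amp and
    # the 0.1 g artifact gate sees every burst
    ge <- g[, ep[m[1]]]
    tr <- rnorm(3); tr <- tr - sum(tr * ge) * ge; tr <- tr / sqrt(sum(tr^2))
    osc <- sin(2 * pi * 5 * tau[m] + runif(1, 0, 2 * pi))
    osc2 <- sin(2 * pi * 3.3 * tau[m] + runif(1, 0, 2 * pi))
    x[, m] <- x[, m] + cfg$burst_amp * (ge %o% (env * osc) +
                                          0.6 * tr %o% (env * osc2))
  }
  acc <- triaxial_signal(x, fs = cfg$acc_fs, start_time = cfg$clock_offset,
                         clock_id = "wearable")
  list(acc = acc,
       rest_mask = epoch_series(rest, start_time = 0, clock_id = "psg"),
       bursts = bursts)
}

#' Simulate a complete synthetic night
#'
#' Composes the hypnogram, beat, waveform and accelerometer generators into
#' one recording with full ground truth. Deterministic given `cfg$seed`.
#'
#' @inheritParams simulate_hypnogram
#' @param include_ecg render the PSG-side ECG channel (needed for clock
#'   synchronization; skipping it speeds up large training simulations).
#' @return a `"synthetic_recording"`: list with `recording` (a
#'   [recording()]), `true_beats` (PSG clock), `true_beats_wearable`,
#'   `rest_mask`, `bursts`, and `clock` (`offset`, `drift`).
#' @export
simulate_recording <- function(cfg, include_ecg = TRUE, seed = cfg$seed) {
  validate_synth_config(cfg)
  maybe_seed(seed)
  hyp <- simulate_hypnogram(cfg, seed = NULL)
  beats <- simulate_beats(cfg, hyp, seed = NULL)
  bursts <- sample_bursts(cfg, hyp, seed = NULL)
  accr <- render_accelerometer(cfg, hyp, bursts = bursts, seed = NULL)
  ppg <- render_ppg(cfg, beats, duration = EPOCH_SEC * n_epochs(hyp),
                    bursts = bursts, seed = NULL)
  ecg <- if (include_ecg)
    render_ecg(cfg, beats, duration = EPOCH_SEC * n_epochs(hyp), seed = NULL)
  rec <- recording(acc = accr$acc, ppg = ppg, ecg = ecg, hypnogram = hyp,
                   meta = list(generator = "wearstage-synthetic",
                               seed = cfg$seed))
  structure(list(recording = rec,
                 true_beats = beats,
                 true_beats_wearable = beats * (1 + cfg$clock_drift) + cfg$clock_offset,
                 rest_mask = accr$rest_mask,
                 bursts = bursts,
                 clock = list(offset = cfg$clock_offset, drift = cfg$clock_drift)),
            class = "synthetic_recording")
}
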