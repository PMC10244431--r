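trim_series <- function(es, E) {
  es$values <- if (is.matrix(es$values)) es$values[seq_len(E), , drop = FALSE]
               else es$values[seq_len(E)]
  es
}

trim_rest_profile <- function(rest, E) {
  rest$likelihood <- trim_series(rest$likelihood, E)
  rest$rest <- trim_series(rest$rest, E)
  flag <- as.logical(rest$rest$values)
  rest$main_rest <- if (any(flag))
    rest$rest$start_time + EPOCH_SEC * c(which(flag)[1] - 1L, max(which(flag)))
  rest
}

#' Prepare the classifier input for one recording
#'
#' The deterministic front end of the staging chain: activity counts,
#' motion features, rest segmentation, motion-gated PPG pulse detection,
#' interbeat intervals and the 10 Hz instantaneous-heart-rate series,
#' assembled into a [assemble_inputs()] object. All series are truncated
#' to the common whole-epoch span.
#'
#' @param rec a [recording()] with accelerometer and PPG channels.
#' @param disc rest discriminant.
#' @param gate_threshold motion gate for pulse detection (g).
#' @return list with `input`, `rest`, `act`, `beats`, `ibi` and a `qc`
#'   list (epoch count, discarded-beat fraction, rest coverage).
#' @export
prepare_stager_input <- function(rec, disc = default_rest_discriminant(),
                                 gate_threshold = 0.1) {
  if (inherits(rec, "synthetic_recording")) rec <- rec$recording
  if (is.null(rec$acc) || is.null(rec$ppg))
    abort_validation("staging needs accelerometer and PPG channels")
  act <- compute_activity_counts(rec$acc)
  feats <- compute_motion_features(rec$acc)
  rest <- segment_rest(feats, disc)
  beats <- detect_ppg_pulses(rec$ppg, rec$acc, threshold_g = gate_threshold)
  ibi <- beats_to_ibi(beats)
  E <- min(length(act$values), length(rest$rest$values))
  act <- trim_series(act, E)
  rest <- trim_rest_profile(rest, E)
  ihr <- ibi_to_ihr(ibi, rest_mask = rest$rest, start_time = act$start_time,
                    n_epochs = E)
  input <- assemble_inputs(ihr, act, rest)
  qc <- list(n_epochs = E,
             discarded_beat_fraction = if (length(beats$times))
               mean(!beats$retained) else NA_real_,
             rest_coverage = mean(as.logical(rest$rest$values)),
             ihr_coverage = mean(input$ihr > 0))
  list(input = input, rest = rest, act = act, beats = beats, ibi = ibi, qc = qc)
}

#' Run the full sleep-staging pipeline on one recording
#'
#' Executes activity counts, rest segmentation, pulse detection, IBI/IHR
#' construction, input assembly and network inference, returning (and
#' optionally writing) the predicted hypnogram, the per-epoch posterior
#' and a QC report. Nights with no detected rest yield an all-Wake
#' hypnogram with a warning.
#'
#' @param rec a [recording()] (or `"synthetic_recording"`).
#' @param model a trained `"sleep_stager"`.
#' @param disc rest discriminant.
#' @param out_prefix optional path prefix; writes
#'   `<prefix>_hypnogram.csv`, `<prefix>_posterior.csv`, `<prefix>_qc.json`.
#' @param gate_threshold motion gate (g) for pulse detection.
#' @return list with `hypnogram`, `posterior`, `qc`.
#' @export
run_stage_pipeline <- function(rec, model, disc = default_rest_discriminant(),
                               out_prefix = NULL, gate_threshold = 0.1) {
  prep <- prepare_stager_input(rec, disc = disc, gate_threshold = gate_threshold)
  if (!any(as.logical(prep$rest$rest$values)))
    warning("no resting epochs detected: output hypnogram is all Wake", call. = FALSE)
  pred <- predict_stages(model, prep$input, rest = prep$rest)
  qc <- prep$qc
  qc$stage_counts <- as.list(table(pred$hypnogram$values))
  if (!is.null(out_prefix)) {
    write_hypnogram(pred$hypnogram, paste0(out_prefix, "_hypnogram.csv"))
    post <- as.data.frame(pred$posterior$values)
    post <- cbind(epoch = seq_len(nrow(post)) - 1L, post)
    write.csv(post, paste0(out_prefix, "_posterior.csv"), row.names = FALSE,
              quote = FALSE)
    jsonlite::write_json(qc, paste0(out_prefix, "_qc.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  list(hypnogram = pred$hypnogram, posterior = pred$posterior, qc = qc)
}
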