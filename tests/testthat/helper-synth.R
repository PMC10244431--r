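# Shared fixtures, built in code and cached for the duration of the test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# a quiet mid-size night with bursts and walking margins
quiet_cfg <- function(...) {
  args <- list(n_epochs = 60, pre_bed_active_minutes = 2,
               post_bed_active_minutes = 1, seed = 101)
  do.call(synth_config, utils::modifyList(args, list(...)))
}

small_night <- function() cached("small_night", simulate_recording(quiet_cfg()))

# a clean night: no movement bursts, no walking
clean_cfg <- function(...) {
  synth_config(n_epochs = 20, pre_bed_active_minutes = 0,
               post_bed_active_minutes = 0, movement_rate = rep(0, 4),
               seed = 202, ...)
}

clean_night <- function() cached("clean_night",
                                 simulate_recording(clean_cfg(), include_ecg = FALSE))

# a tiny stager whose forward/backward is cheap; pools still multiply to 300
tiny_stager_cfg <- function(seed = 1) {
  stager_config(channels = c(3, 4), kernel = 3, dilations = list(c(1, 2), 1),
                n_dense = 2, pools = c(30, 10), gru_hidden = 5, gru_layers = 2,
                seed = seed)
}

# constant-rate beat train renderer inputs
flat_cfg <- function(bpm, ...) {
  args <- list(n_epochs = 10, stage_hr_mean = rep(bpm, 4),
               stage_hr_sd = rep(0, 4), rsa_amp = rep(0, 4), lf_amp = rep(0, 4),
               pre_bed_active_minutes = 0, post_bed_active_minutes = 0,
               movement_rate = rep(0, 4), seed = 7)
  do.call(synth_config, utils::modifyList(args, list(...)))
}

expect_setequal_chr <- function(x, y) testthat::expect_setequal(as.character(x), y)

# a small config whose receptive field still lands in the 5-12 min design
# band, so build_stager() accepts it
tiny_wide_cfg <- function(seed = 11) {
  stager_config(channels = c(4, 6), kernel = 5,
                dilations = list(c(1, 2, 4), c(1, 2, 4)), n_dense = 2,
                pools = c(150, 2), gru_hidden = 6, gru_layers = 2, seed = seed)
}

# strongly separable stage physiology: wide heart-rate separation, low
# jitter, distinctive movement rates (for capacity/overfit checks)
strong_cfg <- function(...) {
  args <- list(n_epochs = 120, pre_bed_active_minutes = 2,
               post_bed_active_minutes = 1,
               transition_matrix = default_transition_matrix(persistence = 0.95),
               stage_hr_mean = c(WAKE = 85, N1N2 = 62, N3 = 50, REM = 72),
               stage_hr_sd = rep(0.5, 4),
               rsa_amp = c(WAKE = 0.5, N1N2 = 2, N3 = 4, REM = 1),
               lf_amp = c(WAKE = 4, N1N2 = 0.5, N3 = 0.2, REM = 3),
               movement_rate = c(WAKE = 1, N1N2 = 0.02, N3 = 0, REM = 0.2),
               seed = 601)
  do.call(synth_config, utils::modifyList(args, list(...)))
}

demo_train_cfg <- function() {
  stager_config(channels = c(6, 8, 12, 16, 24), gru_hidden = 24, seed = 5)
}

# a modestly trained model shared across tests (trained once per run)
demo_model <- function() cached("demo_model", {
  recs <- lapply(501:504, function(s)
    simulate_recording(strong_cfg(seed = s), include_ecg = FALSE))
  ds <- make_dataset(recs)
  fit <- train_stager(build_stager(demo_train_cfg()), ds, val_data = ds,
                      cfg = train_config(lr = 3e-3, max_epochs = 18,
                                         patience = 18, batch_size = 2))
  fit$model
})
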