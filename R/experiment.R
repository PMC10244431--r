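#' Collapse a 4-class confusion matrix onto a merged task
#'
#' Adds rows/columns of the pooled 4-class matrix according to the same
#' merges as [merge_task()]: `"three"` pools N1-N2 and N3 into NREM,
#' `"two"` pools all sleep stages into SLEEP.
#'
#' @param cm a 4 x 4 [confusion_matrix()] in the canonical stage order.
#' @param task `"four"`, `"three"` or `"two"`.
#' @return a [confusion_matrix()] over the merged classes.
#' @export
merge_confusion <- function(cm, task = c("four", "three", "two")) {
  task <- match.arg(task)
  if (task == "four") return(cm)
  groups <- if (task == "three")
    list(WAKE = "WAKE", NREM = c("N1N2", "N3"), REM = "REM")
  else list(WAKE = "WAKE", SLEEP = c("N1N2", "N3", "REM"))
  k <- length(groups)
  out <- matrix(0, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k)) for (j in seq_len(k))
    out[i, j] <- sum(cm[groups[[i]], groups[[j]], drop = FALSE])
  confusion_matrix(out)
}

#' End-to-end synthetic staging experiment
#'
#' The package's self-contained benchmark: simulate training and held-out
#' validation nights, run the full deterministic preparation chain on each,
#' train the conv-GRU stager, and evaluate pooled epoch-per-epoch agreement
#' on the held-out nights. Optionally trains a shuffled-label control
#' (labels permuted within each training night), whose agreement with the
#' true labels must sit at chance.
#'
#' @param train_seeds,val_seeds simulator seeds for training / held-out
#'   nights (the night configuration is otherwise `night_cfg`).
#' @param night_cfg a [synth_config()]; its `seed` is replaced per night.
#' @param model_cfg a [stager_config()]; the default is a reduced-width
#'   variant of the standard architecture so the experiment fits a desktop
#'   CPU budget.
#' @param train_cfg a [train_config()].
#' @param control_nights number of training nights for the shuffled-label
#'   control (`0` skips it).
#' @param control_passes training passes for the control run.
#' @param verbose print per-pass progress.
#' @return list with `kappa4`, `accuracy`, `kappa3`, `kappa2` (pooled over
#'   held-out nights), `confusion` (4 x 4), `control_kappa` (or `NA`),
#'   `model`, `report`.
#' @export
synthetic_experiment <- function(train_seeds = 1:40, val_seeds = 41:50,
                                 night_cfg = synth_config(),
                                 model_cfg = stager_config(
                                   channels = c(6, 8, 12, 16, 24),
                                   gru_hidden = 24, seed = 1),
                                 train_cfg = train_config(lr = 2e-3,
                                                          max_epochs = 12,
                                                          patience = 6,
                                                          min_epochs = 8,
                                                          batch_size = 2),
                                 control_nights = 10, control_passes = 4,
                                 verbose = FALSE) {
  sim <- function(s) {
    cfg <- night_cfg; cfg$seed <- as.integer(s)
    simulate_recording(cfg, include_ecg = FALSE)
  }
  disc <- default_rest_discriminant()
  prep <- function(seeds) make_dataset(lapply(seeds, sim), disc = disc)
  if (verbose) message(sprintf("simulating + preparing %d training nights",
                               length(train_seeds)))
  train_ds <- prep(train_seeds)
  if (verbose) message(sprintf("simulating + preparing %d validation nights",
                               length(val_seeds)))
  val_ds <- prep(val_seeds)
  fit <- train_stager(build_stager(model_cfg), train_ds, val_ds,
                      cfg = train_cfg, verbose = verbose)
  ev <- evaluate_stager(fit$model, val_ds)
  cm <- ev$confusion
  out <- list(kappa4 = ev$kappa, accuracy = ev$accuracy,
              kappa3 = stage_metrics(merge_confusion(cm, "three"))$kappa,
              kappa2 = stage_metrics(merge_confusion(cm, "two"))$kappa,
              confusion = cm, control_kappa = NA_real_,
              model = fit$model, report = fit$report)
  if (control_nights > 0) {
    if (verbose) message("training shuffled-label control")
    sub <- train_ds[seq_len(min(control_nights, length(train_ds)))]
    set.seed(train_cfg$seed + 1L)
    shuf <- lapply(sub, function(it) { it$target <- sample(it$target); it })
    class(shuf) <- class(train_ds)
    ctrl_cfg <- train_cfg
    ctrl_cfg$max_epochs <- as.integer(control_passes)
    ctrl_cfg$patience <- as.integer(control_passes)
    ctrl <- train_stager(build_stager(model_cfg), shuf, val_data = shuf,
                         cfg = ctrl_cfg)
    out$control_kappa <- evaluate_stager_params(ctrl$model$params, model_cfg,
                                                sub)$kappa
  }
  out
}
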