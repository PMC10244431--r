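#' Training configuration for the sleep stager
#'
#' Adam with a fixed learning rate, whole recordings as batch elements
#' (padding epochs are masked out of the loss), unweighted categorical
#' cross-entropy (no sample or class weighting — class imbalance in sleep
#' data stays within roughly 1:4 and the gradient is not dominated by the
#' majority class), and early stopping on pooled validation kappa — model
#' selection is aligned with the headline agreement metric, not the loss.
#' A focal-loss exponent is exposed for experimentation but off by
#' default.
#'
#' @param lr Adam learning rate.
#' @param max_epochs maximum training passes over the data.
#' @param patience validation passes without kappa improvement before
#'   stopping.
#' @param min_epochs minimum passes before early stopping may trigger
#'   (sequence models often sit on a majority-class plateau for several
#'   passes before the minority stages emerge).
#' @param batch_size recordings per gradient step.
#' @param focal_gamma focal-loss exponent (0 = plain cross-entropy).
#' @param clip_norm global gradient-norm clip (recurrent stacks occasionally
#'   produce exploding steps); `Inf` disables clipping.
#' @param seed seed for shuffling.
#' @return a `"train_config"`.
#' @export
train_config <- function(lr = 1e-3, max_epochs = 30, patience = 10,
                         min_epochs = 1, batch_size = 4, focal_gamma = 0,
                         clip_norm = 5, seed = 42L) {
  if (lr <= 0) abort_validation("lr must be > 0")
  if (patience < 1) abort_validation("patience must be >= 1")
  structure(list(lr = lr, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 min_epochs = as.integer(min_epochs),
                 batch_size = as.integer(batch_size),
                 focal_gamma = focal_gamma, clip_norm = clip_norm,
                 seed = as.integer(seed)),
            class = "train_config")
}

trim_epochs <- function(item, E) {
  within(item, {
    input$ihr <- input$ihr[seq_len(E * EPOCH_SEC * IHR_FS)]
    input$act <- input$act[seq_len(E)]
    input$rest <- input$rest[seq_len(E)]
    input$n_epochs <- E
    target <- target[seq_len(E)]
    mask <- mask[seq_len(E)]
  })
}

#' Build a supervised dataset from recordings
#'
#' Runs the deterministic preparation chain (activity counts, motion
#' features, rest segmentation, PPG pulse detection with motion gating,
#' IBI, 10 Hz IHR, input assembly) on each recording and pairs it with the
#' simplified 4-class targets of its reference hypnogram. Epochs labelled
#' `UNSCORED` are masked out of the loss. Recordings whose scored epochs do
#' not intersect the recording span are skipped with a warning.
#'
#' @param recordings list of `"synthetic_recording"` objects, or
#'   [recording()]s carrying a reference hypnogram.
#' @param hypnograms optional list overriding the reference hypnograms;
#'   entries may be [hypnogram()]s or raw scorer label vectors interpreted
#'   under `scheme`.
#' @param scheme scorer vocabulary for raw label vectors (`"AASM"`/`"RK"`).
#' @param disc rest discriminant (default: the shipped synthetic-trained
#'   one).
#' @return a `"stager_dataset"`: list of `(input, target, mask, id)`.
#' @export
make_dataset <- function(recordings, hypnograms = NULL, scheme = "AASM",
                         disc = default_rest_discriminant()) {
  items <- list()
  for (i in seq_along(recordings)) {
    r <- recordings[[i]]
    rec <- if (inherits(r, "synthetic_recording")) r$recording else r
    hyp <- if (!is.null(hypnograms)) {
      h <- hypnograms[[i]]
      if (inherits(h, "hypnogram")) h
      else hypnogram(simplify_labels(h, scheme = scheme))
    } else rec$hypnogram
    if (is.null(hyp)) abort_validation(sprintf("recording %d has no hypnogram", i))
    prep <- prepare_stager_input(rec, disc = disc)
    target <- as.integer(stage_factor(hyp$values))
    mask <- as.character(hyp$values) != "UNSCORED"
    E <- min(prep$input$n_epochs, length(target))
    if (E < 1L || !any(mask[seq_len(E)])) {
      warning(sprintf("recording %d has no scored epochs overlapping the span; skipped", i),
              call. = FALSE)
      next
    }
    items[[length(items) + 1L]] <-
      trim_epochs(list(input = prep$input, target = target, mask = mask,
                       id = rec$meta$id %||% i), E)
  }
  structure(items, class = "stager_dataset")
}

# masked (optionally focal) cross-entropy on softmax columns; returns the
# summed loss and the gradient w.r.t. the logits (unnormalised)
masked_ce <- function(post, target, mask, gamma = 0) {
  idx <- which(mask)
  pt <- pmax(post[cbind(target[idx], idx)], 1e-12)
  onehot <- matrix(0, nrow(post), ncol(post))
  onehot[cbind(target[idx], idx)] <- 1
  if (gamma == 0) {
    loss <- -sum(log(pt))
    dlog <- post - onehot
    dlog[, setdiff(seq_len(ncol(post)), idx)] <- 0
  } else {
    w <- (1 - pt)^gamma
    loss <- -sum(w * log(pt))
    dLdpt <- gamma * (1 - pt)^(gamma - 1) * log(pt) - w / pt
    dlog <- matrix(0, nrow(post), ncol(post))
    for (j in seq_along(idx)) {
      c0 <- idx[j]; tt <- target[c0]
      delta <- as.numeric(seq_len(nrow(post)) == tt)
      dlog[, c0] <- dLdpt[j] * post[tt, c0] * (delta - post[, c0])
    }
  }
  list(loss = loss, n = length(idx), dlogits = dlog)
}

#' Train the sleep stager
#'
#' Mini-batch Adam over whole recordings with masked unweighted
#' cross-entropy; after every pass the pooled validation kappa is computed
#' and the best checkpoint retained (early stopping after `patience`
#' passes without improvement). Deterministic given the seeds in the model
#' and training configurations.
#'
#' @param model an untrained (or pre-trained) `"sleep_stager"`.
#' @param train_data,val_data `"stager_dataset"`s; `val_data = NULL`
#'   disables early stopping and keeps the final weights.
#' @param cfg a [train_config()].
#' @param verbose print per-pass progress.
#' @return list with `model` (best checkpoint) and `report`
#'   (`"train_report"`: per-batch loss, per-pass validation kappa and
#'   accuracy, best pass).
#' @export
train_stager <- function(model, train_data, val_data = NULL,
                         cfg = train_config(), verbose = FALSE) {
  if (length(train_data) < 1L) abort_validation("need at least one training recording")
  set.seed(cfg$seed)
  params <- model$params
  mcfg <- model$config
  m <- lapply(params, function(p) p * 0)   # zero state, same shape as params
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; tstep <- 0
  losses <- numeric(0); val_k <- numeric(0); val_a <- numeric(0)
  best <- list(kappa = -Inf, params = params, pass = 0L)
  wait <- 0L
  for (pass in seq_len(cfg$max_epochs)) {
    ord <- sample.int(length(train_data))
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      batch <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      grads <- NULL; loss_sum <- 0; n_sum <- 0
      for (i in batch) {
        it <- train_data[[i]]
        fw <- stager_forward(params, mcfg, it$input$ihr, it$input$act,
                             need_cache = TRUE)
        ce <- masked_ce(fw$posterior, it$target, it$mask, cfg$focal_gamma)
        loss_sum <- loss_sum + ce$loss; n_sum <- n_sum + ce$n
        g <- stager_backward(params, mcfg, fw$cache, ce$dlogits)
        grads <- if (is.null(grads)) g
                 else mapply(`+`, grads, g[names(grads)], SIMPLIFY = FALSE)
      }
      loss <- loss_sum / n_sum
      if (!is.finite(loss))
        abort_ws(sprintf("non-finite loss at pass %d: check inputs/learning rate", pass),
                 "wearstage_train_error")
      losses <- c(losses, loss)
      tstep <- tstep + 1
      gnorm <- sqrt(sum(vapply(grads, function(g) sum((g / n_sum)^2), 0)))
      gscale <- if (is.finite(cfg$clip_norm) && gnorm > cfg$clip_norm)
        cfg$clip_norm / gnorm else 1
      for (nm in names(params)) {
        g <- gscale * grads[[nm]] / n_sum
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g * g
        params[[nm]] <- params[[nm]] - cfg$lr * (m[[nm]] / (1 - b1^tstep)) /
          (sqrt(v[[nm]] / (1 - b2^tstep)) + eps)
      }
    }
    if (!is.null(val_data)) {
      ev <- evaluate_stager_params(params, mcfg, val_data)
      val_k <- c(val_k, ev$kappa); val_a <- c(val_a, ev$accuracy)
      if (verbose)
        message(sprintf("pass %d: loss %.4f, val kappa %.3f", pass,
                        mean(tail(losses, length(train_data) %/% cfg$batch_size + 1)),
                        ev$kappa))
      if (is.finite(ev$kappa) && ev$kappa > best$kappa + 1e-4) {
        best <- list(kappa = ev$kappa, params = params, pass = pass)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (pass >= cfg$min_epochs && wait >= cfg$patience) break
      }
    } else if (verbose) {
      message(sprintf("pass %d: loss %.4f", pass, tail(losses, 1)))
    }
  }
  if (is.null(val_data)) best <- list(kappa = NA_real_, params = params,
                                      pass = length(val_k))
  out <- model
  out$params <- best$params
  out$trained <- TRUE
  out$history <- structure(list(loss = losses, val_kappa = val_k,
                                val_accuracy = val_a, best_pass = best$pass),
                           class = "train_report")
  list(model = out, report = out$history)
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf("<train report: %d gradient steps", length(x$loss)))
  if (length(x$val_kappa))
    cat(sprintf(", best validation kappa %.3f at pass %d",
                max(x$val_kappa, na.rm = TRUE), x$best_pass))
  cat(">\n")
  invisible(x)
}

evaluate_stager_params <- function(params, mcfg, dataset) {
  cm <- matrix(0, 4, 4, dimnames = list(STAGES, STAGES))
  for (it in dataset) {
    fw <- stager_forward(params, mcfg, it$input$ihr, it$input$act)
    pred <- apply(fw$posterior, 2, which.max)
    keep <- which(it$mask)
    cm <- cm + unclass(table(factor(STAGES[it$target[keep]], levels = STAGES),
                             factor(STAGES[pred[keep]], levels = STAGES)))
  }
  list(kappa = kappa_from_counts(cm), accuracy = sum(diag(cm)) / sum(cm),
       confusion = confusion_matrix(cm))
}

#' Pooled evaluation of a stager on a dataset
#'
#' Pools the masked epochs of every recording into one confusion matrix
#' and reports kappa and accuracy.
#'
#' @param model a `"sleep_stager"`.
#' @param dataset a `"stager_dataset"`.
#' @return list `kappa`, `accuracy`, `confusion`.
#' @export
evaluate_stager <- function(model, dataset) {
  evaluate_stager_params(model$params, model$config, dataset)
}
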