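SELU_ALPHA <- 1.6732632423543772
SELU_LAMBDA <- 1.0507009873554805
ACT_SCALE_REF <- 1000  # activity scaling: log1p(count) / log1p(1000)

selu <- function(x) SELU_LAMBDA * ifelse(x > 0, x, SELU_ALPHA * (exp(x) - 1))
selu_grad <- function(x) SELU_LAMBDA * ifelse(x > 0, 1, SELU_ALPHA * exp(x))

#' Sleep-stager architecture configuration
#'
#' The feature extractor is a stack of residual convolutional blocks
#' interleaved with max-pooling. Each block applies dilated 1-D
#' convolutions (SELU activations), concatenates the block input to the
#' conv output (skip connection; concatenation rather than addition
#' preserves SELU's self-normalising statistics), and mixes with kernel-1
#' dense layers. The pooling factors multiply to exactly 300, taking the
#' 10 Hz instantaneous-heart-rate input to one 64-dimensional feature
#' vector per 30-s epoch. The per-epoch activity count joins after the
#' extractor (concatenated to the epoch feature — the only junction
#' consistent with the two input rates without upsampling). Three stacked
#' bidirectional GRUs with a concatenated skip around the stack feed a
#' 4-way softmax. Default dilation schedules give a receptive field of
#' about 8.1 min, comparable to the longest rolling window of classic
#' HRV-feature stagers (8.5 min).
#'
#' @param channels conv width per residual block.
#' @param kernel odd conv kernel length.
#' @param dilations list of per-block dilation schedules.
#' @param n_dense kernel-1 dense layers per block.
#' @param pools max-pool factor after each block (product must be 300).
#' @param gru_hidden GRU hidden units per direction.
#' @param gru_layers number of stacked bidirectional GRU layers.
#' @param n_classes output classes (Wake, N1-N2, N3, REM).
#' @param seed seed for the self-normalising weight initialisation.
#' @return a `"stager_config"`.
#' @export
stager_config <- function(channels = c(16, 24, 32, 48, 64),
                          kernel = 5,
                          dilations = c(rep(list(c(1, 2, 4)), length(channels) - 1),
                                        list(1)),
                          n_dense = 2,
                          pools = c(5, 5, 4, 3, 1),
                          gru_hidden = 64,
                          gru_layers = 3,
                          n_classes = 4,
                          seed = 1L) {
  if (is.matrix(dilations)) dilations <- asplit(dilations, 1)
  if (!is.list(dilations)) dilations <- list(dilations)
  cfg <- structure(list(channels = as.integer(channels), kernel = as.integer(kernel),
                        dilations = lapply(dilations, as.integer),
                        n_dense = as.integer(n_dense), pools = as.integer(pools),
                        gru_hidden = as.integer(gru_hidden),
                        gru_layers = as.integer(gru_layers),
                        n_classes = as.integer(n_classes),
                        input_fs = IHR_FS, seed = as.integer(seed)),
                   class = "stager_config")
  if (cfg$kernel %% 2L != 1L) abort_validation("kernel length must be odd")
  if (length(cfg$pools) != length(cfg$channels) ||
      length(cfg$dilations) != length(cfg$channels))
    abort_validation("channels, pools and dilations must have one entry per block")
  if (prod(cfg$pools) != cfg$input_fs * EPOCH_SEC)
    abort_validation(sprintf("pooling factors must multiply to %d (one feature per 30 s)",
                             cfg$input_fs * EPOCH_SEC))
  cfg
}

#' Receptive field of the feature extractor
#'
#' Closed-form recursion over layers: each dilated convolution widens the
#' receptive field by `(k - 1) * dilation * prod(pools so far)` input
#' samples; kernel-1 dense layers add nothing.
#'
#' @param cfg a [stager_config()].
#' @return list with `samples`, `seconds`, `minutes`.
#' @export
receptive_field <- function(cfg) {
  r <- 1; cum <- 1
  for (b in seq_along(cfg$channels)) {
    for (d in cfg$dilations[[b]]) r <- r + (cfg$kernel - 1) * d * cum
    cum <- cum * cfg$pools[b]
  }
  list(samples = r, seconds = r / cfg$input_fs, minutes = r / cfg$input_fs / 60)
}

block_in_channels <- function(cfg) c(1L, cfg$channels[-length(cfg$channels)])

init_stager_params <- function(cfg) {
  set.seed(cfg$seed)
  p <- list()
  rn <- function(n, fan_in) rnorm(n, 0, 1 / sqrt(fan_in))
  cin <- block_in_channels(cfg)
  for (b in seq_along(cfg$channels)) {
    cb <- cfg$channels[b]
    ci <- cin[b]
    for (j in seq_along(cfg$dilations[[b]])) {
      inw <- if (j == 1) ci else cb
      p[[sprintf("blk%d.conv%d.W", b, j)]] <-
        array(rn(cb * inw * cfg$kernel, inw * cfg$kernel), dim = c(cb, inw, cfg$kernel))
      p[[sprintf("blk%d.conv%d.b", b, j)]] <- numeric(cb)
    }
    for (j in seq_len(cfg$n_dense)) {
      inw <- if (j == 1) cb + ci else cb
      p[[sprintf("blk%d.dense%d.W", b, j)]] <- matrix(rn(cb * inw, inw), cb, inw)
      p[[sprintf("blk%d.dense%d.b", b, j)]] <- numeric(cb)
    }
  }
  H <- cfg$gru_hidden
  feat <- cfg$channels[length(cfg$channels)]
  i1 <- feat + 1L
  for (l in seq_len(cfg$gru_layers)) {
    inw <- if (l == 1) i1 else 2L * H
    for (dir in c("fwd", "bwd")) {
      p[[sprintf("gru%d.%s.W", l, dir)]] <- matrix(rn(3 * H * inw, inw), 3 * H, inw)
      p[[sprintf("gru%d.%s.U", l, dir)]] <- matrix(rn(3 * H * H, H), 3 * H, H)
      p[[sprintf("gru%d.%s.b", l, dir)]] <- numeric(3 * H)
    }
  }
  fcat <- i1 + 2L * H
  # zero-initialised output layer: the initial posterior is exactly uniform,
  # so the starting cross-entropy equals ln(n_classes)
  p[["out.W"]] <- matrix(0, cfg$n_classes, fcat)
  p[["out.b"]] <- numeric(cfg$n_classes)
  p
}

#' Build the conv-GRU sleep stager
#'
#' Instantiates the network of [stager_config()] with self-normalising
#' (SELU-scheme, `N(0, 1/fan_in)`) weights drawn deterministically from
#' `cfg$seed`. The receptive field must land between 5 and 12 minutes.
#'
#' @param cfg a [stager_config()].
#' @return a `"sleep_stager"` model object (untrained).
#' @export
build_stager <- function(cfg) {
  rf <- receptive_field(cfg)
  if (rf$minutes < 5 || rf$minutes > 12)
    abort_validation(sprintf("receptive field %.1f min outside the 5-12 min design band",
                             rf$minutes))
  structure(list(config = cfg, params = init_stager_params(cfg),
                 trained = FALSE, history = NULL),
            class = "sleep_stager")
}

#' @export
print.sleep_stager <- function(x, ...) {
  cfg <- x$config
  rf <- receptive_field(cfg)
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<sleep_stager: %d conv blocks (%s), %d biGRU x %d, %s, %d parameters>\n",
              length(cfg$channels), paste(cfg$channels, collapse = "-"),
              cfg$gru_layers, cfg$gru_hidden,
              if (x$trained) "trained" else "untrained", np))
  cat(sprintf("  receptive field %.1f min; %d-class softmax per 30-s epoch\n",
              rf$minutes, cfg$n_classes))
  invisible(x)
}

#' @export
summary.sleep_stager <- function(object, ...) {
  print(object)
  m <- count_macs(object$config, duration_h = 1)
  cat(sprintf("  MACs/h: %.1fM feature extraction + %.1fM recurrent = %.1fM\n",
              m$feature_extractor / 1e6, m$recurrent / 1e6, m$total / 1e6))
  if (!is.null(object$history) && length(object$history$val_kappa))
    cat(sprintf("  best validation kappa %.3f\n", max(object$history$val_kappa, na.rm = TRUE)))
  invisible(object)
}

## ---------------------------------------------------------------------------
## Forward / backward

stager_forward <- function(params, cfg, ihr_scaled, act_scaled, need_cache = FALSE) {
  x <- matrix(ihr_scaled, nrow = 1)
  cin <- block_in_channels(cfg)
  cache <- list(blocks = vector("list", length(cfg$channels)))
  for (b in seq_along(cfg$channels)) {
    bc <- list(X = x, conv_in = list(), conv_pre = list(), dense_in = list(),
               dense_pre = list())
    h <- x
    for (j in seq_along(cfg$dilations[[b]])) {
      W <- params[[sprintf("blk%d.conv%d.W", b, j)]]
      pre <- cpp_conv1d_fwd(h, W, params[[sprintf("blk%d.conv%d.b", b, j)]],
                            cfg$dilations[[b]][j])
      if (need_cache) { bc$conv_in[[j]] <- h; bc$conv_pre[[j]] <- pre }
      h <- cpp_selu(pre)
    }
    y <- rbind(bc$X, h)                       # skip concatenation
    for (j in seq_len(cfg$n_dense)) {
      W <- params[[sprintf("blk%d.dense%d.W", b, j)]]
      pre <- W %*% y + params[[sprintf("blk%d.dense%d.b", b, j)]]
      if (need_cache) { bc$dense_in[[j]] <- y; bc$dense_pre[[j]] <- pre }
      y <- cpp_selu(pre)
    }
    if (cfg$pools[b] > 1L) {
      pl <- cpp_maxpool_fwd(y, cfg$pools[b])
      if (need_cache) { bc$pool_idx <- pl$idx; bc$pre_pool_len <- ncol(y) }
      y <- pl$Y
    }
    if (need_cache) cache$blocks[[b]] <- bc
    x <- y
  }
  feat <- x                                    # 64 x E
  x1 <- rbind(feat, matrix(act_scaled, nrow = 1))
  cache$x1 <- x1
  g_in <- x1
  cache$gru <- vector("list", cfg$gru_layers)
  for (l in seq_len(cfg$gru_layers)) {
    fw <- cpp_gru_fwd(g_in, params[[sprintf("gru%d.fwd.W", l)]],
                      params[[sprintf("gru%d.fwd.U", l)]],
                      params[[sprintf("gru%d.fwd.b", l)]], FALSE)
    bw <- cpp_gru_fwd(g_in, params[[sprintf("gru%d.bwd.W", l)]],
                      params[[sprintf("gru%d.bwd.U", l)]],
                      params[[sprintf("gru%d.bwd.b", l)]], TRUE)
    if (need_cache) cache$gru[[l]] <- list(input = g_in, fwd = fw, bwd = bw)
    g_in <- rbind(fw$H, bw$H)
  }
  xc <- rbind(x1, g_in)                        # skip around the GRU stack
  cache$xc <- xc
  logits <- params[["out.W"]] %*% xc + params[["out.b"]]
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  post <- sweep(e, 2, colSums(e), "/")
  list(posterior = post, logits = logits, cache = if (need_cache) cache)
}

stager_backward <- function(params, cfg, cache, dlogits) {
  g <- list()
  g[["out.W"]] <- dlogits %*% t(cache$xc)
  g[["out.b"]] <- rowSums(dlogits)
  dxc <- t(params[["out.W"]]) %*% dlogits
  i1 <- nrow(cache$x1)
  dx1 <- dxc[seq_len(i1), , drop = FALSE]
  dg <- dxc[-seq_len(i1), , drop = FALSE]
  H <- cfg$gru_hidden
  for (l in rev(seq_len(cfg$gru_layers))) {
    cc <- cache$gru[[l]]
    din <- matrix(0, nrow(cc$input), ncol(cc$input))
    for (dir in c("fwd", "bwd")) {
      dH <- if (dir == "fwd") dg[seq_len(H), , drop = FALSE]
            else dg[H + seq_len(H), , drop = FALSE]
      r <- cpp_gru_bwd(cc$input, params[[sprintf("gru%d.%s.W", l, dir)]],
                       params[[sprintf("gru%d.%s.U", l, dir)]],
                       cc[[dir]]$H, cc[[dir]]$Z, cc[[dir]]$R, cc[[dir]]$N,
                       dH, dir == "bwd")
      g[[sprintf("gru%d.%s.W", l, dir)]] <- r$dW
      g[[sprintf("gru%d.%s.U", l, dir)]] <- r$dU
      g[[sprintf("gru%d.%s.b", l, dir)]] <- as.numeric(r$db)
      din <- din + r$dX
    }
    dg <- din
  }
  dx1 <- dx1 + dg                              # gradient w.r.t. x1 (features + act)
  dfeat <- dx1[seq_len(i1 - 1L), , drop = FALSE]
  dy <- dfeat
  for (b in rev(seq_along(cfg$channels))) {
    bc <- cache$blocks[[b]]
    if (cfg$pools[b] > 1L)
      dy <- cpp_maxpool_bwd(dy, bc$pool_idx, bc$pre_pool_len)
    for (j in rev(seq_len(cfg$n_dense))) {
      dpre <- cpp_selu_grad_mul(bc$dense_pre[[j]], dy)
      g[[sprintf("blk%d.dense%d.W", b, j)]] <- dpre %*% t(bc$dense_in[[j]])
      g[[sprintf("blk%d.dense%d.b", b, j)]] <- rowSums(dpre)
      dy <- t(params[[sprintf("blk%d.dense%d.W", b, j)]]) %*% dpre
    }
    nin <- nrow(bc$X)
    dX_skip <- dy[seq_len(nin), , drop = FALSE]
    dh <- dy[-seq_len(nin), , drop = FALSE]
    for (j in rev(seq_along(cfg$dilations[[b]]))) {
      dpre <- cpp_selu_grad_mul(bc$conv_pre[[j]], dh)
      r <- cpp_conv1d_bwd(bc$conv_in[[j]], params[[sprintf("blk%d.conv%d.W", b, j)]],
                          dpre, cfg$dilations[[b]][j])
      g[[sprintf("blk%d.conv%d.W", b, j)]] <- r$dW
      g[[sprintf("blk%d.conv%d.b", b, j)]] <- as.numeric(r$db)
      dh <- r$dX
    }
    dy <- dX_skip + dh
  }
  g
}

## ---------------------------------------------------------------------------
## Input assembly and inference

#' Assemble the classifier input for one night
#'
#' Applies the frozen affine input maps — IHR in bpm divided by 60 (the 0
#' no-data sentinel is preserved exactly), activity counts mapped through
#' `log1p(count) / log1p(1000)` — and zeroes the IHR of epochs flagged
#' non-rest. Activity counts are never zeroed: the classifier uses high
#' counts as evidence of Wake.
#'
#' @param ihr an `ihr_series` (10 Hz).
#' @param act an [epoch_series()] of activity counts.
#' @param rest a `"rest_profile"` from [segment_rest()], or `NULL`.
#' @return a `"stager_input"`: `ihr` (length `300 E`), `act` (length E),
#'   `rest` (logical E), `n_epochs`, `start_time`, `clock_id`.
#' @export
assemble_inputs <- function(ihr, act, rest = NULL) {
  E <- length(act$values)
  if (length(ihr$values) != E * EPOCH_SEC * IHR_FS)
    abort_validation(sprintf("IHR length %d does not match %d epochs",
                             length(ihr$values), E))
  if (abs(ihr$start_time - act$start_time) > 1e-6)
    abort_validation("IHR and activity series must share the epoch grid")
  rest_flags <- if (is.null(rest)) rep(TRUE, E) else as.logical(rest$rest$values)
  if (length(rest_flags) != E)
    abort_validation("rest profile length does not match the activity series")
  ihr_scaled <- ihr$values / 60
  ihr_scaled[rep(!rest_flags, each = EPOCH_SEC * IHR_FS)] <- 0
  structure(list(ihr = ihr_scaled,
                 act = log1p(pmax(act$values, 0)) / log1p(ACT_SCALE_REF),
                 rest = rest_flags, n_epochs = E,
                 start_time = act$start_time, clock_id = act$clock_id),
            class = "stager_input")
}

#' Predict sleep stages for one night
#'
#' Runs the network over the whole recording (the bidirectional context is
#' the full night), takes the per-epoch argmax, and forces epochs outside
#' the main resting period to Wake in the output hypnogram (the posterior
#' is left untouched).
#'
#' @param model a `"sleep_stager"`.
#' @param input a `"stager_input"`.
#' @param rest optional `"rest_profile"` delimiting the main resting
#'   period.
#' @return list with `posterior` ([epoch_series()] of E x 4 rows summing
#'   to 1) and `hypnogram` (predicted [hypnogram()]).
#' @export
predict_stages <- function(model, input, rest = NULL) {
  if (!inherits(model, "sleep_stager")) abort_validation("`model` must be a sleep_stager")
  if (input$n_epochs < 1L) abort_validation("input shorter than one epoch")
  fw <- stager_forward(model$params, model$config, input$ihr, input$act)
  post <- t(fw$posterior)
  colnames(post) <- STAGES[seq_len(model$config$n_classes)]
  labels <- STAGES[apply(fw$posterior, 2, which.max)]
  if (!is.null(rest)) labels[!in_main_rest(rest)] <- "WAKE"
  list(posterior = epoch_series(post, start_time = input$start_time,
                                clock_id = input$clock_id),
       hypnogram = hypnogram(labels, start_time = input$start_time,
                             clock_id = input$clock_id))
}

#' @export
predict.sleep_stager <- function(object, newdata, rest = NULL, ...) {
  predict_stages(object, newdata, rest = rest)
}

#' Multiply-accumulate operation count of the stager
#'
#' Bookkeeping of the network's computational cost: a conv layer costs
#' `Cin * Cout * k * L_out` MACs, a kernel-1 dense layer `Cin * Cout * L`,
#' a bidirectional GRU `2 * 3 * H * (H + X + 1)` per time step, plus the
#' output projection. Totals scale exactly linearly in recording duration.
#'
#' @param cfg a [stager_config()].
#' @param duration_h recording duration in hours.
#' @return list `feature_extractor`, `recurrent`, `total` (MACs for the
#'   given duration).
#' @export
count_macs <- function(cfg, duration_h) {
  L <- duration_h * 3600 * cfg$input_fs
  E <- duration_h * 3600 / EPOCH_SEC
  cin <- block_in_channels(cfg)
  fe <- 0
  for (b in seq_along(cfg$channels)) {
    cb <- cfg$channels[b]
    for (j in seq_along(cfg$dilations[[b]])) {
      inw <- if (j == 1) cin[b] else cb
      fe <- fe + inw * cb * cfg$kernel * L
    }
    for (j in seq_len(cfg$n_dense)) {
      inw <- if (j == 1) cb + cin[b] else cb
      fe <- fe + inw * cb * L
    }
    L <- L / cfg$pools[b]
  }
  H <- cfg$gru_hidden
  i1 <- cfg$channels[length(cfg$channels)] + 1
  rec <- 0
  for (l in seq_len(cfg$gru_layers)) {
    inw <- if (l == 1) i1 else 2 * H
    rec <- rec + E * 2 * 3 * H * (H + inw + 1)
  }
  rec <- rec + E * cfg$n_classes * (i1 + 2 * H)
  list(feature_extractor = fe, recurrent = rec, total = fe + rec)
}

## ---------------------------------------------------------------------------
## Checkpoint: JSON header (config + parameter manifest) + float64 payload

#' Save / load a stager checkpoint
#'
#' Single-file checkpoint: magic line, 8-byte little-endian header length,
#' JSON header embedding the [stager_config()] and a parameter manifest
#' (names and dimensions in canonical order), then all parameters as
#' float64 little-endian.
#'
#' @param model a `"sleep_stager"`.
#' @param path checkpoint path.
#' @export
save_stager <- function(model, path) {
  cfg <- model$config
  manifest <- lapply(model$params, function(a) dim(a) %||% length(a))
  hdr <- list(config = unclass(cfg), manifest = manifest,
              trained = model$trained)
  raw_hdr <- charToRaw(as.character(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA)))
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("WSCKPT1\n", con, eos = NULL)
  writeBin(as.integer(c(length(raw_hdr), 0)), con, size = 4, endian = "little")
  writeBin(raw_hdr, con)
  for (nm in names(model$params))
    writeBin(as.numeric(model$params[[nm]]), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname save_stager
#' @export
load_stager <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readChar(con, 8, useBytes = TRUE)
  if (!identical(magic, "WSCKPT1\n")) abort_io("not a wearstage checkpoint")
  len <- readBin(con, "integer", n = 2, size = 4, endian = "little")[1]
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = len)),
                            simplifyVector = TRUE)
  cfgl <- hdr$config
  cfg <- stager_config(channels = cfgl$channels, kernel = cfgl$kernel,
                       dilations = cfgl$dilations, n_dense = cfgl$n_dense,
                       pools = cfgl$pools, gru_hidden = cfgl$gru_hidden,
                       gru_layers = cfgl$gru_layers, n_classes = cfgl$n_classes,
                       seed = cfgl$seed)
  params <- list()
  for (nm in names(hdr$manifest)) {
    d <- hdr$manifest[[nm]]
    x <- readBin(con, "numeric", n = prod(d), size = 8, endian = "little")
    params[[nm]] <- if (length(d) > 1) array(x, dim = d) else x
  }
  structure(list(config = cfg, params = params,
                 trained = isTRUE(hdr$trained), history = NULL),
            class = "sleep_stager")
}
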