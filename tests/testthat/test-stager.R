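test_that("stager configuration is validated and receptive field follows the recursion", {
  expect_error(stager_config(pools = c(5, 5, 4, 2, 1)),
               class = "wearstage_validation_error", regexp = "300")
  expect_error(stager_config(kernel = 4), class = "wearstage_validation_error")

  # independent layer-by-layer recursion: r <- r + (k-1) * d * prod(pools)
  cfg <- stager_config()
  r <- 1; cum <- 1
  for (b in seq_along(cfg$channels)) {
    for (d in cfg$dilations[[b]]) r <- r + (cfg$kernel - 1) * d * cum
    cum <- cum * cfg$pools[b]
  }
  expect_equal(receptive_field(cfg)$samples, r)
  expect_gt(receptive_field(cfg)$minutes, 5)
  expect_lt(receptive_field(cfg)$minutes, 12)

  # a configuration whose receptive field blows past the design band
  big <- stager_config(dilations = rep(list(c(1, 2, 4)), 5))
  expect_error(build_stager(big), class = "wearstage_validation_error",
               regexp = "receptive field")
})

test_that("receptive-field recursion matches input-perturbation probing", {
  cfg <- tiny_stager_cfg(seed = 3)
  params <- wearstage:::init_stager_params(cfg)
  params$out.W <- matrix(rnorm(length(params$out.W), 0, 0.3),
                         nrow(params$out.W))
  E <- 5
  set.seed(20)
  ihr <- rnorm(300 * E, 1, 0.2)
  act <- runif(E)
  base <- wearstage:::stager_forward(params, cfg, ihr, act, need_cache = TRUE)
  nf <- length(cfg$channels)
  feat_of <- function(ihr_mod) {
    fw <- wearstage:::stager_forward(params, cfg, ihr_mod, act, need_cache = TRUE)
    fw$cache$x1[seq_len(nrow(fw$cache$x1) - 1L), 3]   # conv feature, epoch 3
  }
  rf <- receptive_field(cfg)$samples
  half <- (rf - 1) / 2
  # epoch 3 pools input samples 601..900; with the receptive-field halo the
  # feature depends on samples (601 - half) .. (900 + half) and nothing else
  probe <- function(i) {
    x <- ihr; x[i] <- x[i] + 25
    max(abs(feat_of(x) - base$cache$x1[seq_len(nrow(base$cache$x1) - 1L), 3]))
  }
  expect_gt(probe(750), 0)
  expect_gt(probe(601 - half + 2), 0)
  expect_gt(probe(900 + half - 2), 0)
  expect_equal(probe(601 - half - 3), 0)
  expect_equal(probe(900 + half + 3), 0)
})

test_that("building a stager is deterministic and yields normalised posteriors", {
  cfg <- tiny_stager_cfg(seed = 11)
  m1 <- build_stager(tiny_wide_cfg())
  m2 <- build_stager(tiny_wide_cfg())
  sums1 <- vapply(m1$params, function(p) sum(p^2), 0)
  expect_identical(sums1, vapply(m2$params, function(p) sum(p^2), 0))

  E <- 4
  set.seed(21)
  input <- structure(list(ihr = pmax(rnorm(300 * E, 1, .2), 0), act = runif(E),
                          rest = rep(TRUE, E), n_epochs = E, start_time = 0,
                          clock_id = "wearable"),
                     class = "stager_input")
  pred <- predict_stages(m1, input)
  post <- pred$posterior$values
  expect_equal(dim(post), c(E, 4L))
  expect_equal(unname(rowSums(post)), rep(1, E), tolerance = 1e-6)
  expect_true(all(as.character(pred$hypnogram$values) %in%
                  c("WAKE", "N1N2", "N3", "REM")))
})

test_that("input assembly applies the frozen scalings and rest zeroing", {
  E <- 3
  ihr <- structure(list(values = rep(60, 300 * E), fs = 10, start_time = 0,
                        clock_id = "wearable"), class = "ihr_series")
  act <- epoch_series(c(0, 10, 1000), start_time = 0)
  rest <- structure(list(rest = epoch_series(c(TRUE, FALSE, TRUE), start_time = 0)),
                    class = "rest_profile")
  inp <- assemble_inputs(ihr, act, rest)
  expect_equal(inp$ihr[1:300], rep(1, 300))              # 60 bpm -> 1.0
  expect_equal(inp$ihr[301:600], rep(0, 300))            # non-rest epoch zeroed
  expect_equal(inp$act, log1p(c(0, 10, 1000)) / log1p(1000))
  expect_equal(inp$act[1], 0)                            # log1p(0) = 0
  expect_equal(inp$act[2], log1p(10) / log1p(1000))      # activity untouched by rest

  bad_act <- epoch_series(c(0, 10), start_time = 0)
  expect_error(assemble_inputs(ihr, bad_act, NULL),
               class = "wearstage_validation_error")
})

test_that("epochs outside the main resting period are forced to Wake", {
  m <- build_stager(tiny_wide_cfg())
  E <- 6
  set.seed(22)
  input <- structure(list(ihr = pmax(rnorm(300 * E, 1, .2), 0), act = runif(E),
                          rest = rep(TRUE, E), n_epochs = E, start_time = 0,
                          clock_id = "wearable"), class = "stager_input")
  prof <- structure(list(rest = epoch_series(c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
                                             start_time = 0),
                         main_rest = c(60, 150)),
                    class = "rest_profile")
  pred <- predict_stages(m, input, rest = prof)
  lab <- as.character(pred$hypnogram$values)
  expect_identical(lab[c(1, 2, 6)], rep("WAKE", 3))
  # the posterior itself is left untouched by the override
  expect_equal(unname(rowSums(pred$posterior$values)), rep(1, E), tolerance = 1e-6)
})

test_that("MAC accounting matches closed forms and an independent tabulation", {
  # a single conv layer: Cin=1, Cout=4, k=3 over 1 h of 10 Hz input
  cfg1 <- stager_config(channels = 4, kernel = 3, dilations = list(1),
                        n_dense = 0, pools = 300, gru_layers = 0, gru_hidden = 1)
  m1h <- count_macs(cfg1, duration_h = 1)
  expect_equal(m1h$feature_extractor, 1 * 4 * 3 * 36000)  # 432,000

  cfg <- stager_config()
  m1 <- count_macs(cfg, 1); m2 <- count_macs(cfg, 2)
  expect_equal(m2$total, 2 * m1$total)
  expect_equal(m1$total, m1$feature_extractor + m1$recurrent)

  # independent tabulation: build an explicit layer table and sum it
  tab <- 0
  L <- 36000
  cin <- 1
  for (b in seq_along(cfg$channels)) {
    cb <- cfg$channels[b]
    widths_in <- c(cin, rep(cb, length(cfg$dilations[[b]]) - 1))
    for (w in widths_in) tab <- tab + w * cb * cfg$kernel * L
    tab <- tab + (cb + cin) * cb * L + cb * cb * L
    L <- L / cfg$pools[b]
    cin <- cb
  }
  expect_equal(m1$feature_extractor, tab)
  gru_tab <- 0
  E <- 120
  for (l in 1:3) {
    xin <- if (l == 1) 65 else 128
    gru_tab <- gru_tab + E * 2 * 3 * 64 * (64 + xin + 1)
  }
  gru_tab <- gru_tab + E * 4 * (65 + 128)
  expect_equal(m1$recurrent, gru_tab)
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- tiny_stager_cfg(seed = 2)
  params <- wearstage:::init_stager_params(cfg)
  params$out.W <- matrix(rnorm(length(params$out.W), 0, 0.2), nrow(params$out.W))
  set.seed(6)
  E <- 3
  ihr <- rnorm(300 * E, 1, 0.3)   # smooth, non-degenerate (no max-pool ties)
  act <- runif(E)
  target <- sample(1:4, E, TRUE)
  mask <- c(TRUE, TRUE, FALSE)
  loss_fn <- function(p) {
    fw <- wearstage:::stager_forward(p, cfg, ihr, act)
    ce <- wearstage:::masked_ce(fw$posterior, target, mask)
    ce$loss / ce$n
  }
  fw <- wearstage:::stager_forward(params, cfg, ihr, act, need_cache = TRUE)
  ce <- wearstage:::masked_ce(fw$posterior, target, mask)
  g <- wearstage:::stager_backward(params, cfg, fw$cache, ce$dlogits / ce$n)
  eps <- 1e-6
  set.seed(7)
  for (nm in names(params)) {
    for (ix in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
      p2 <- params; p2[[nm]][ix] <- p2[[nm]][ix] + eps
      p3 <- params; p3[[nm]][ix] <- p3[[nm]][ix] - eps
      num <- (loss_fn(p2) - loss_fn(p3)) / (2 * eps)
      expect_equal(g[[nm]][ix], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, ix))
    }
  }
})

test_that("an all-zero input night yields (near-)identical posteriors away from the edges", {
  cfg <- tiny_stager_cfg(seed = 13)
  params <- wearstage:::init_stager_params(cfg)
  params$out.W <- matrix(rnorm(length(params$out.W), 0, 0.3), nrow(params$out.W))
  E <- 60
  fw <- wearstage:::stager_forward(params, cfg, rep(0, 300 * E), rep(0, E))
  mid <- fw$posterior[, 20:40]
  expect_lt(max(abs(mid - rowMeans(mid))), 1e-3)
})

test_that("checkpoints round-trip the configuration and parameters exactly", {
  m <- build_stager(tiny_wide_cfg())
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_stager(m, f)
  m2 <- load_stager(f)
  expect_equal(m2$config$channels, m$config$channels)
  expect_equal(m2$config$dilations, m$config$dilations)
  for (nm in names(m$params)) expect_identical(m2$params[[nm]], m$params[[nm]])

  E <- 3
  set.seed(23)
  input <- structure(list(ihr = pmax(rnorm(300 * E, 1, .2), 0), act = runif(E),
                          rest = rep(TRUE, E), n_epochs = E, start_time = 0,
                          clock_id = "wearable"), class = "stager_input")
  expect_identical(predict_stages(m, input)$posterior$values,
                   predict_stages(m2, input)$posterior$values)
})
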