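#' @useDynLib wearstage, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx rnorm runif rpois rbinom quantile shapiro.test
#'   qsignrank median sd fft cor var predict
#' @importFrom utils read.csv write.csv head tail
NULL

# Canonical 4-class stage vocabulary (+ UNSCORED sentinel). Order is frozen:
# every confusion matrix, posterior column and transition matrix uses it.
STAGES <- c("WAKE", "N1N2", "N3", "REM")
STAGES_ALL <- c(STAGES, "UNSCORED")

EPOCH_SEC <- 30
IHR_FS <- 10

stage_factor <- function(x) factor(as.character(x), levels = STAGES_ALL)

abort_ws <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "wearstage_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

abort_validation <- function(msg, ...) abort_ws(msg, "wearstage_validation_error", ...)
abort_io <- function(msg, ...) abort_ws(msg, "wearstage_io_error", ...)

stopifnot_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    abort_validation(sprintf("`%s` must be a finite scalar in [%g, %g]", name, lower, upper))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
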