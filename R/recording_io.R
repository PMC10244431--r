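#' Timestamped signal containers
#'
#' All signals carry `start_time` (seconds, 64-bit float, relative to the
#' epoch 0 of a named clock), a sampling frequency `fs` (Hz) and a `clock_id`
#' label. Channels of one recording may live on different clocks (e.g. the
#' wearable's wrist unit vs. the PSG amplifier); [synchronize_clocks()]
#' estimates the mapping between them.
#'
#' @param samples for `triaxial_signal()` a 3 x N numeric matrix of
#'   acceleration in g (rows = x, y, z axes); for `waveform()` a numeric
#'   vector in arbitrary units.
#' @param fs sampling frequency in Hz (> 0).
#' @param start_time time of the first sample in seconds on `clock_id`.
#' @param clock_id label of the clock the timestamps refer to.
#' @param kind waveform modality, `"ppg"` or `"ecg"`.
#' @return An object of class `"triaxial_signal"` or `"waveform"`.
#' @export
triaxial_signal <- function(samples, fs, start_time = 0, clock_id = "wearable") {
  samples <- as.matrix(samples)
  if (nrow(samples) != 3L) abort_validation("triaxial samples must be a 3 x N matrix")
  if (length(samples) && !all(is.finite(samples)))
    abort_validation("triaxial samples must be finite")
  stopifnot_scalar_num(fs, "fs", lower = .Machine$double.eps)
  structure(
    list(samples = samples, fs = as.numeric(fs),
         start_time = as.numeric(start_time), clock_id = clock_id),
    class = "triaxial_signal"
  )
}

#' @rdname triaxial_signal
#' @export
waveform <- function(samples, fs, kind = c("ppg", "ecg"), start_time = 0,
                     clock_id = "wearable") {
  kind <- match.arg(kind)
  samples <- as.numeric(samples)
  if (length(samples) && !all(is.finite(samples)))
    abort_validation("waveform samples must be finite")
  stopifnot_scalar_num(fs, "fs", lower = .Machine$double.eps)
  structure(
    list(samples = samples, fs = as.numeric(fs), kind = kind,
         start_time = as.numeric(start_time), clock_id = clock_id),
    class = "waveform"
  )
}

#' Per-epoch series and hypnograms
#'
#' An `epoch_series` holds one value (or one row of values) per 30-s epoch.
#' Epoch `i` (0-based) covers the half-open interval
#' `[start_time + 30 i, start_time + 30 (i + 1))`. A `hypnogram` is an epoch
#' series over the frozen stage vocabulary `WAKE, N1N2, N3, REM, UNSCORED`
#' with an optional lights-off interval `[t_on, t_off)` over which a
#' reference scorer assessed the night.
#'
#' @param values numeric vector (or E x K matrix) of per-epoch values.
#' @param labels character/factor vector of stage labels in the 5-symbol
#'   vocabulary.
#' @param start_time,clock_id as in [triaxial_signal()].
#' @param epoch_len epoch length in seconds (fixed at 30).
#' @param lights_off numeric `c(t_on, t_off)` in seconds on `clock_id`, or
#'   `NULL` when unknown.
#' @return An `"epoch_series"` / `"hypnogram"` object.
#' @export
epoch_series <- function(values, start_time = 0, clock_id = "wearable",
                         epoch_len = EPOCH_SEC) {
  if (epoch_len != EPOCH_SEC) abort_validation("epoch_len is fixed at 30 s")
  structure(
    list(values = values, start_time = as.numeric(start_time),
         clock_id = clock_id, epoch_len = EPOCH_SEC),
    class = "epoch_series"
  )
}

#' @rdname epoch_series
#' @export
hypnogram <- function(labels, start_time = 0, clock_id = "psg",
                      lights_off = NULL) {
  labels <- stage_factor(labels)
  if (anyNA(labels))
    abort_validation("hypnogram labels must be in {WAKE, N1N2, N3, REM, UNSCORED}")
  h <- epoch_series(labels, start_time = start_time, clock_id = clock_id)
  if (!is.null(lights_off)) {
    if (length(lights_off) != 2L || !all(is.finite(lights_off)) ||
        lights_off[2] <= lights_off[1])
      abort_validation("lights_off must be c(t_on, t_off) with t_off > t_on")
    span <- c(h$start_time, h$start_time + EPOCH_SEC * length(labels))
    if (lights_off[1] < span[1] - 1e-9 || lights_off[2] > span[2] + 1e-9)
      abort_validation("lights_off must lie within the recording span")
    h$lights_off <- as.numeric(lights_off)
  }
  class(h) <- c("hypnogram", class(h))
  h
}

#' @export
length.epoch_series <- function(x) if (is.matrix(x$values)) nrow(x$values) else length(x$values)

#' Number of epochs and epoch/time conversion
#'
#' Conversions are exact for the half-open epoch convention: a time `t` maps
#' to epoch `floor((t - start_time) / 30)`, so no instant belongs to two
#' epochs.
#'
#' @param x an `epoch_series`.
#' @param time numeric vector of times in seconds on the series' clock.
#' @param i integer vector of 0-based epoch indices.
#' @return `n_epochs()`: epoch count; `epoch_of()`: 0-based indices;
#'   `epoch_start()`: start times in seconds.
#' @export
n_epochs <- function(x) length.epoch_series(x)

#' @rdname n_epochs
#' @export
epoch_of <- function(x, time) as.integer(floor((time - x$start_time) / x$epoch_len))

#' @rdname n_epochs
#' @export
epoch_start <- function(x, i) x$start_time + x$epoch_len * i

#' A multi-channel wearable/PSG recording
#'
#' Bundles the optional channels of one night: triaxial accelerometer, PPG
#' and ECG waveforms, and a reference hypnogram, plus free-form metadata.
#' At least one channel must be present.
#'
#' @param acc `triaxial_signal` or `NULL`.
#' @param ppg,ecg `waveform` or `NULL`.
#' @param hypnogram reference `hypnogram` or `NULL`.
#' @param meta named list of metadata (id, device, notes, ...).
#' @return A `"recording"` object.
#' @export
recording <- function(acc = NULL, ppg = NULL, ecg = NULL, hypnogram = NULL,
                      meta = list()) {
  if (is.null(acc) && is.null(ppg) && is.null(ecg) && is.null(hypnogram))
    abort_validation("no channels: a recording needs at least one channel")
  if (!is.null(acc) && !inherits(acc, "triaxial_signal"))
    abort_validation("`acc` must be a triaxial_signal")
  for (nm in c("ppg", "ecg")) {
    w <- get(nm)
    if (!is.null(w)) {
      if (!inherits(w, "waveform")) abort_validation(sprintf("`%s` must be a waveform", nm))
      if (w$kind != nm) abort_validation(sprintf("`%s` waveform has kind '%s'", nm, w$kind))
    }
  }
  structure(list(acc = acc, ppg = ppg, ecg = ecg, hypnogram = hypnogram,
                 meta = meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat("<wearstage recording>\n")
  if (!is.null(x$acc))
    cat(sprintf("  acc: %d samples @ %g Hz [%s]\n", ncol(x$acc$samples), x$acc$fs, x$acc$clock_id))
  for (nm in c("ppg", "ecg")) if (!is.null(x[[nm]]))
    cat(sprintf("  %s: %d samples @ %g Hz [%s]\n", nm, length(x[[nm]]$samples),
                x[[nm]]$fs, x[[nm]]$clock_id))
  if (!is.null(x$hypnogram))
    cat(sprintf("  hypnogram: %d epochs [%s]\n", n_epochs(x$hypnogram), x$hypnogram$clock_id))
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Archive container (.wsa): magic line, 8-byte little-endian header length,
## UTF-8 JSON header describing channels, then raw float64 (little-endian)
## payload blocks in header order. Layout documented in the README.

ARCHIVE_MAGIC <- "WSARCH1\n"

archive_payloads <- function(rec) {
  pl <- list(); hdr <- list(channels = list())
  if (!is.null(rec$acc)) {
    hdr$channels$acc <- list(fs = rec$acc$fs, start_time = rec$acc$start_time,
                             clock_id = rec$acc$clock_id, n = ncol(rec$acc$samples))
    pl$acc <- as.numeric(rec$acc$samples)  # column-major 3 x N
  }
  for (nm in c("ppg", "ecg")) if (!is.null(rec[[nm]])) {
    w <- rec[[nm]]
    hdr$channels[[nm]] <- list(fs = w$fs, start_time = w$start_time,
                               clock_id = w$clock_id, kind = w$kind,
                               n = length(w$samples))
    pl[[nm]] <- w$samples
  }
  if (!is.null(rec$hypnogram)) {
    h <- rec$hypnogram
    hdr$channels$hypnogram <- list(start_time = h$start_time, clock_id = h$clock_id,
                                   n = n_epochs(h), levels = STAGES_ALL)
    if (!is.null(h$lights_off)) hdr$channels$hypnogram$lights_off <- h$lights_off
    pl$hypnogram <- as.numeric(as.integer(h$values))
  }
  if (length(rec$meta)) hdr$meta <- rec$meta
  list(header = hdr, payloads = pl)
}

#' Save / load the single-file recording archive
#'
#' The archive is a self-contained binary container: an ASCII magic line, an
#' 8-byte little-endian unsigned header length, a JSON header naming each
#' channel with its sampling metadata, and one float64 little-endian block
#' per channel. `load_recording(save_recording(x, p), "archive")` returns an
#' object equal field-by-field to `x`, and saving the same recording twice
#' produces byte-identical files.
#'
#' @param rec a [recording()].
#' @param path file path (conventionally `.wsa`).
#' @return `save_recording()` returns `path` invisibly; `load_recording()`
#'   returns a [recording()].
#' @export
save_recording <- function(rec, path) {
  if (!inherits(rec, "recording")) abort_validation("`rec` must be a recording")
  ap <- archive_payloads(rec)
  hdr <- charToRaw(as.character(jsonlite::toJSON(ap$header, auto_unbox = TRUE, digits = NA)))
  con <- tryCatch(file(path, "wb"), error = function(e) abort_io(conditionMessage(e)),
                  warning = function(w) abort_io(conditionMessage(w)))
  on.exit(close(con))
  writeChar(ARCHIVE_MAGIC, con, eos = NULL)
  len <- length(hdr)
  writeBin(as.integer(c(len %% 2^31, 0)), con, size = 4, endian = "little")
  writeBin(hdr, con)
  for (p in ap$payloads) writeBin(p, con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname save_recording
#' @param format `"archive"` (read/write container) or `"edf"` (read-only
#'   waveform ingestion, see [read_edf()]).
#' @param ... passed on to [read_edf()] for `format = "edf"`.
#' @export
load_recording <- function(path, format = c("archive", "edf"), ...) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_io(sprintf("cannot read '%s': no such file", path))
  if (format == "edf") return(read_edf(path, ...))
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readChar(con, nchar(ARCHIVE_MAGIC), useBytes = TRUE)
  if (!identical(magic, ARCHIVE_MAGIC)) abort_io("not a wearstage archive")
  len <- readBin(con, "integer", n = 2, size = 4, endian = "little")[1]
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = len)),
                            simplifyVector = TRUE)
  if (length(hdr$channels) == 0L) abort_validation("no channels in archive")
  chans <- list()
  for (nm in names(hdr$channels)) {
    ch <- hdr$channels[[nm]]
    n <- as.integer(ch$n)
    nvals <- if (nm == "acc") 3L * n else n
    x <- readBin(con, "numeric", n = nvals, size = 8, endian = "little")
    chans[[nm]] <- switch(nm,
      acc = triaxial_signal(matrix(x, nrow = 3L), fs = ch$fs,
                            start_time = ch$start_time, clock_id = ch$clock_id),
      ppg = ,
      ecg = waveform(x, fs = ch$fs, kind = ch$kind, start_time = ch$start_time,
                     clock_id = ch$clock_id),
      hypnogram = hypnogram(ch$levels[as.integer(x)], start_time = ch$start_time,
                            clock_id = ch$clock_id,
                            lights_off = ch$lights_off %||% NULL)
    )
  }
  recording(acc = chans$acc, ppg = chans$ppg, ecg = chans$ecg,
            hypnogram = chans$hypnogram,
            meta = as.list(hdr$meta %||% list()))
}

## ---------------------------------------------------------------------------
## EDF reader (waveforms only; EDF annotations are never parsed — hypnograms
## always come through the CSV dialect).

read_ascii_fields <- function(con, widths) {
  vapply(widths, function(w) trimws(readChar(con, w, useBytes = TRUE)), "")
}

#' Read waveform channels from an EDF file
#'
#' A minimal reader for the European Data Format: fixed-layout ASCII header,
#' 16-bit little-endian samples scaled by the per-signal physical/digital
#' calibration. Channel names are mapped to recording roles through
#' `channel_map`; channels not named there are ignored with a warning.
#'
#' @param path EDF file path.
#' @param channel_map named list mapping roles to EDF signal labels:
#'   `list(acc = c("Acc X","Acc Y","Acc Z"), ppg = "PPG", ecg = "ECG")`.
#'   Roles may be omitted; a named label missing from the file is a
#'   validation error.
#' @param clock_id clock label assigned to all channels read from this file.
#' @param start_time start time (s) assigned to the first sample.
#' @return A [recording()].
#' @export
read_edf <- function(path, channel_map, clock_id = "edf", start_time = 0) {
  con <- file(path, "rb"); on.exit(close(con))
  hd <- read_ascii_fields(con, c(8, 80, 80, 8, 8, 8, 44, 8, 8, 4))
  n_rec <- as.integer(hd[8]); rec_dur <- as.numeric(hd[9]); ns <- as.integer(hd[10])
  if (is.na(ns) || ns < 1L) abort_io("unreadable EDF header")
  sig_field <- function(w) vapply(seq_len(ns), function(i) trimws(readChar(con, w, useBytes = TRUE)), "")
  labels <- sig_field(16)
  sig_field(80); sig_field(8)                       # transducer, physical dim
  pmin <- as.numeric(sig_field(8)); pmax <- as.numeric(sig_field(8))
  dmin <- as.numeric(sig_field(8)); dmax <- as.numeric(sig_field(8))
  sig_field(80)                                     # prefilter
  spr <- as.integer(sig_field(8))                   # samples per record
  sig_field(32)                                     # reserved
  raw <- readBin(con, "integer", n = sum(spr) * n_rec, size = 2, endian = "little")
  scale <- (pmax - pmin) / (dmax - dmin)
  sig <- vector("list", ns)
  offs <- c(0L, cumsum(spr))
  per_rec <- sum(spr)
  for (i in seq_len(ns)) {
    idx <- as.vector(outer(seq_len(spr[i]) + offs[i], (seq_len(n_rec) - 1L) * per_rec, `+`))
    sig[[i]] <- pmin[i] + (raw[idx] - dmin[i]) * scale[i]
  }
  names(sig) <- labels
  fs <- spr / rec_dur
  names(fs) <- labels
  wanted <- unlist(channel_map, use.names = FALSE)
  missing_ch <- setdiff(wanted, labels)
  if (length(missing_ch))
    abort_validation(sprintf("EDF is missing mapped channel(s): %s",
                             paste(missing_ch, collapse = ", ")))
  unused <- setdiff(labels, wanted)
  if (length(unused))
    warning(sprintf("ignoring unmapped EDF channel(s): %s", paste(unused, collapse = ", ")),
            call. = FALSE)
  acc <- NULL
  if (!is.null(channel_map$acc)) {
    axes <- channel_map$acc
    if (length(axes) != 3L) abort_validation("channel_map$acc must name 3 axes")
    if (length(unique(fs[axes])) != 1L)
      abort_validation("accelerometer axes must share one sampling rate")
    acc <- triaxial_signal(do.call(rbind, sig[axes]), fs = fs[[axes[1]]],
                           start_time = start_time, clock_id = clock_id)
  }
  mk_wave <- function(role) {
    if (is.null(channel_map[[role]])) return(NULL)
    lab <- channel_map[[role]]
    waveform(sig[[lab]], fs = fs[[lab]], kind = role, start_time = start_time,
             clock_id = clock_id)
  }
  recording(acc = acc, ppg = mk_wave("ppg"), ecg = mk_wave("ecg"),
            meta = list(source = basename(path)))
}

## ---------------------------------------------------------------------------
## Hypnogram CSV dialect: `epoch,label[,lights_off]`

#' Read / write hypnogram CSV files
#'
#' One row per 30-s epoch: a contiguous 0-based (or shifted) epoch index, a
#' stage label in the AASM (`W,N1,N2,N3,R,?`) or R&K (`W,S1,S2,S3,S4,R,MT`)
#' vocabulary, and an optional 0/1 `lights_off` flag column. Labels are
#' simplified to the 4-class vocabulary via [simplify_labels()]; symbols
#' outside the dialect become `UNSCORED` with a warning. `write_hypnogram()`
#' emits AASM-style tokens (`N1N2` is written as `N2`) so its output reads
#' back to the identical 4-class hypnogram.
#'
#' @param path CSV path.
#' @param dialect scoring vocabulary of the file, `"aasm"` or `"rk"`.
#' @param start_time,clock_id passed to [hypnogram()]; a first epoch index
#'   `k > 0` shifts the start time by `30 k` seconds.
#' @param h a [hypnogram()] to write.
#' @return `read_hypnogram()`: a [hypnogram()].
#' @export
read_hypnogram <- function(path, dialect = c("aasm", "rk"), start_time = 0,
                           clock_id = "psg") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_io(sprintf("cannot read '%s': no such file", path))
  df <- read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  if (!all(c("epoch", "label") %in% names(df)))
    abort_validation("hypnogram CSV needs columns `epoch,label[,lights_off]`")
  idx <- as.integer(df$epoch)
  if (nrow(df) && any(diff(idx) != 1L))
    abort_validation("non-contiguous epoch indices in hypnogram CSV")
  lab <- toupper(trimws(as.character(df$label)))
  vocab <- if (dialect == "aasm") c("W", "N1", "N2", "N3", "R", "?")
           else c("W", "S1", "S2", "S3", "S4", "R", "MT")
  unknown <- !(lab %in% vocab)
  if (any(unknown)) {
    warning(sprintf("%d unknown label(s) (%s) mapped to UNSCORED", sum(unknown),
                    paste(unique(lab[unknown]), collapse = ", ")), call. = FALSE)
    lab[unknown] <- if (dialect == "aasm") "?" else "MT"
  }
  labels4 <- simplify_labels(lab, scheme = toupper(dialect))
  st <- start_time + EPOCH_SEC * (if (length(idx)) idx[1] else 0L)
  lo <- NULL
  if ("lights_off" %in% names(df) && any(df$lights_off > 0)) {
    on_idx <- which(df$lights_off > 0)
    lo <- st + EPOCH_SEC * c(min(on_idx) - 1L, max(on_idx))
  }
  hypnogram(labels4, start_time = st, clock_id = clock_id, lights_off = lo)
}

#' @rdname read_hypnogram
#' @export
write_hypnogram <- function(h, path) {
  if (!inherits(h, "hypnogram")) abort_validation("`h` must be a hypnogram")
  token <- c(WAKE = "W", N1N2 = "N2", N3 = "N3", REM = "R", UNSCORED = "?")
  df <- data.frame(epoch = seq_len(n_epochs(h)) - 1L,
                   label = unname(token[as.character(h$values)]))
  if (!is.null(h$lights_off)) {
    starts <- epoch_start(h, df$epoch)
    df$lights_off <- as.integer(starts >= h$lights_off[1] - 1e-9 &
                                starts < h$lights_off[2] - 1e-9)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
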