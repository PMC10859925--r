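#' Construct a continuous multichannel recording
#'
#' The raw substrate of the pipeline: a channels x samples numeric matrix
#' (microvolts) with a sampling rate and ordered channel labels.
#'
#' @param signal Numeric matrix, channels in rows, samples in columns.
#' @param sfreq Sampling rate in samples per second.
#' @param channel_names Character vector of channel labels, one per row.
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(signal, sfreq,
                                 channel_names = rownames(signal)) {
  signal <- as.matrix(signal)
  if (!is.numeric(signal)) abort("signal must be numeric")
  if (!is.numeric(sfreq) || length(sfreq) != 1 || sfreq <= 0) {
    abort("sfreq must be a positive scalar")
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(signal)))
  }
  if (length(channel_names) != nrow(signal)) {
    abort("channel_names length must equal the number of signal rows")
  }
  if (anyNA(signal)) {
    bad <- which(is.na(signal), arr.ind = TRUE)[1, ]
    abort(sprintf("NaN/NA sample at channel %s (row %d), sample %d",
                  channel_names[bad[1]], bad[1], bad[2]))
  }
  rownames(signal) <- channel_names
  structure(
    list(signal = signal, sfreq = sfreq, channel_names = channel_names),
    class = "continuous_recording"
  )
}

#' @export
#' @method print continuous_recording
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$sfreq,
              ncol(x$signal) / x$sfreq))
  invisible(x)
}

#' Load a continuous recording from disk
#'
#' Supported formats: `"edf"` (European Data Format, continuous recordings
#' with a common sampling rate across signals), `"delimited"` (numeric text
#' table, channels as rows or columns), and `"binary"` (headerless little-
#' endian doubles with a JSON sidecar `<path>.json` holding `n_channels`,
#' `sfreq` and optionally `channel_names` and `byrow`).
#'
#' @param path Path to the file.
#' @param format One of `"edf"`, `"delimited"`, `"binary"`. Defaults to a
#'   guess from the file extension.
#' @param sfreq Sampling rate (required for delimited input).
#' @param channels_in One of `"rows"`, `"columns"`: orientation of a
#'   delimited table.
#' @param sep Field separator for delimited input.
#' @param channel_names Optional channel labels for delimited input without
#'   a header column.
#' @return A [continuous_recording()].
#' @export
load_recording <- function(path, format = c("auto", "edf", "delimited", "binary"),
                           sfreq = NULL, channels_in = c("rows", "columns"),
                           sep = ",", channel_names = NULL) {
  format <- match.arg(format)
  channels_in <- match.arg(channels_in)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      edf = "edf", csv = "delimited", tsv = "delimited", txt = "delimited",
      bin = "binary",
      abort(paste0("cannot guess format from extension '.", ext,
                   "'; pass format explicitly"))
    )
  }
  switch(format,
    edf = read_edf(path),
    delimited = {
      if (is.null(sfreq)) abort("sfreq is required for delimited input")
      tab <- utils::read.table(path, sep = sep, header = FALSE)
      m <- as.matrix(tab)
      if (!is.numeric(m)) abort("delimited file contains non-numeric cells")
      if (channels_in == "columns") m <- t(m)
      continuous_recording(m, sfreq, channel_names)
    },
    binary = {
      sidecar <- paste0(path, ".json")
      if (!file.exists(sidecar)) {
        abort(paste0("binary input needs a JSON sidecar at ", sidecar))
      }
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      if (is.null(meta$n_channels) || is.null(meta$sfreq)) {
        abort("sidecar must declare n_channels and sfreq")
      }
      raw <- readBin(path, what = "double", n = file.size(path) / 8,
                     size = 8, endian = "little")
      nc <- as.integer(meta$n_channels)
      if (length(raw) %% nc != 0) {
        abort("binary length is not a multiple of n_channels")
      }
      byrow <- isTRUE(meta$byrow)
      m <- matrix(raw, nrow = nc, byrow = byrow)
      continuous_recording(m, meta$sfreq, meta$channel_names %||% channel_names)
    }
  )
}

# Minimal EDF reader: continuous EDF with identical sampling rates across
# ordinary signals; annotation channels are dropped. Header layout follows
# the published EDF field widths (ASCII, fixed offsets).
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256L, useBytes = TRUE)
  field <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  n_records <- as.integer(field(hdr, 237, 8))
  record_dur <- as.numeric(field(hdr, 245, 8))
  ns <- as.integer(field(hdr, 253, 4))
  if (is.na(ns) || ns < 1) abort("malformed EDF header: signal count")
  sig_hdr <- readChar(con, 256L * ns, useBytes = TRUE)
  take <- function(width, offset) {
    vapply(seq_len(ns), function(i) {
      trimws(substr(sig_hdr, offset + (i - 1) * width + 1, offset + i * width))
    }, character(1))
  }
  labels <- take(16, 0)
  # offsets are cumulative over the per-field blocks of the signal header
  off <- 16 * ns                       # transducer
  off <- off + 80 * ns                 # physical dimension
  phys_dim_off <- off; off <- off + 8 * ns
  phys_min <- as.numeric(take(8, off)); off <- off + 8 * ns
  phys_max <- as.numeric(take(8, off)); off <- off + 8 * ns
  dig_min <- as.numeric(take(8, off)); off <- off + 8 * ns
  dig_max <- as.numeric(take(8, off)); off <- off + 8 * ns
  off <- off + 80 * ns                 # prefiltering
  nsamp <- as.integer(take(8, off))
  keep <- !grepl("EDF Annotations", labels, fixed = TRUE)
  if (!any(keep)) abort("EDF contains no ordinary signals")
  if (length(unique(nsamp[keep])) != 1) {
    abort("EDF signals with differing sampling rates are not supported")
  }
  if (record_dur <= 0) abort("malformed EDF header: record duration")
  sfreq <- nsamp[keep][1] / record_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  gain[!is.finite(gain)] <- 1
  total <- sum(nsamp)
  out <- matrix(NA_real_, nrow = sum(keep), ncol = n_records * nsamp[keep][1])
  col0 <- 0L
  for (r in seq_len(n_records)) {
    rec <- readBin(con, "integer", n = total, size = 2, signed = TRUE,
                   endian = "little")
    if (length(rec) < total) abort("EDF truncated mid-record")
    pos <- 0L
    ki <- 0L
    for (s in seq_len(ns)) {
      vals <- rec[(pos + 1):(pos + nsamp[s])]
      pos <- pos + nsamp[s]
      if (!keep[s]) next
      ki <- ki + 1L
      out[ki, (col0 + 1):(col0 + nsamp[s])] <-
        phys_min[s] + gain[s] * (vals - dig_min[s])
    }
    col0 <- col0 + nsamp[keep][1]
  }
  continuous_recording(out, sfreq, labels[keep])
}

#' Split a continuous recording into fixed-length epochs
#'
#' Non-overlapping windows of `epoch_len_s` seconds; a trailing partial
#' window is discarded. Epochs are 0-based and `epoch_index` records each
#' retained epoch's original position in the continuous record.
#'
#' @param rec A [continuous_recording()].
#' @param epoch_len_s Epoch length in seconds; `epoch_len_s * sfreq` must be
#'   a whole number of samples.
#' @return An `epoched_recording`: list with `data` (epochs x channels x
#'   samples array), `epoch_len_s`, `sfreq`, `channel_names`, `epoch_index`.
#' @examples
#' rec <- continuous_recording(matrix(rnorm(2 * 1000), 2), sfreq = 100)
#' epoch_signal(rec, 1)
#' @export
epoch_signal <- function(rec, epoch_len_s = 1) {
  stopifnot(inherits(rec, "continuous_recording"))
  spe <- epoch_len_s * rec$sfreq
  if (abs(spe - round(spe)) > 1e-9 || spe <= 0) {
    abort("epoch_len_s * sfreq must be a positive integer number of samples")
  }
  spe <- as.integer(round(spe))
  n_total <- ncol(rec$signal)
  n_epochs <- n_total %/% spe
  if (n_epochs < 1) abort("recording shorter than one epoch")
  used <- rec$signal[, seq_len(n_epochs * spe), drop = FALSE]
  data <- aperm(array(used, dim = c(nrow(used), spe, n_epochs)), c(3, 1, 2))
  structure(
    list(data = data, epoch_len_s = epoch_len_s, sfreq = rec$sfreq,
         channel_names = rec$channel_names,
         epoch_index = seq_len(n_epochs) - 1L),
    class = "epoched_recording"
  )
}

#' @export
#' @method print epoched_recording
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_recording> %d epochs x %d channels x %d samples (%g s @ %g Hz)\n",
              d[1], d[2], d[3], x$epoch_len_s, x$sfreq))
  invisible(x)
}

n_epochs <- function(x) dim(x$data)[1]

# subset retained epochs, keeping the original-position bookkeeping
subset_epochs <- function(epochs, keep) {
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$epoch_index <- epochs$epoch_index[keep]
  epochs
}
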