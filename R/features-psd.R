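#' Band- and region-averaged adaptive multitaper power
#'
#' For each epoch and channel an adaptive multitaper PSD is estimated
#' (Slepian tapers, Thomson adaptive weights), averaged over the frequency
#' bins inside each band, then channel-averaged within each region of
#' interest. With 5 bands and 15 regions this yields the 75 power columns
#' that drive artifact rejection and feed the SDA after transformation.
#'
#' @param epochs An `epoched_recording` from [epoch_signal()].
#' @param bands A [band_scheme()].
#' @param rois A [roi_map()] covering all channels of the recording.
#' @param nw Time half-bandwidth product of the tapers.
#' @param n_tapers Number of tapers (default `2 * nw - 1`).
#' @return A [feature_table()] with `psd` columns named
#'   `psd_<band>_<region>`; band metadata carries the band name.
#' @export
compute_band_roi_psd <- function(epochs, bands = band_scheme(),
                                 rois = roi_map_15(), nw = 4,
                                 n_tapers = 2 * nw - 1) {
  stopifnot(inherits(epochs, "epoched_recording"))
  d <- dim(epochs$data)
  if (epochs$sfreq < 2 * max(bands$high)) {
    abort("sampling rate below twice the top band edge")
  }
  if (d[3] <= n_tapers) abort("epoch shorter than the taper support")
  check_roi_coverage(rois, epochs$channel_names)
  tp <- dpss_tapers(d[3], nw = nw, k = n_tapers)
  freqs <- (seq_len(d[3] %/% 2 + 1) - 1) * epochs$sfreq / d[3]
  fb <- band_of_freq(freqs, bands)
  used <- !is.na(fb)
  if (!any(used)) abort("no frequency bins fall inside the bands")
  band_names <- bands$band
  # per-channel adaptive PSD, then per-band frequency means
  band_power <- array(NA_real_, dim = c(d[1], d[2], length(band_names)))
  for (e in seq_len(d[1])) {
    spec <- epoch_eigenspectra(epochs$data[e, , , drop = TRUE], tp)
    for (ch in seq_len(d[2])) {
      sk <- Mod(spec[, ch, , drop = TRUE])^2
      if (is.null(dim(sk))) sk <- matrix(sk, ncol = 1)
      s <- adaptive_psd(sk, tp$eigenvalues, var_x = var(epochs$data[e, ch, ]))
      for (b in seq_along(band_names)) {
        band_power[e, ch, b] <- mean(s[which(fb == band_names[b])])
      }
    }
  }
  # channel-average within regions
  regions <- unique(rois$region)
  cols <- list()
  meta <- list()
  for (b in seq_along(band_names)) {
    for (r in regions) {
      chs <- match(rois$channel[rois$region == r], epochs$channel_names)
      chs <- chs[!is.na(chs)]
      cols[[length(cols) + 1L]] <-
        rowMeans(band_power[, chs, b, drop = FALSE])
      meta[[length(meta) + 1L]] <- tibble::tibble(
        feature = paste("psd", band_names[b], r, sep = "_"),
        kind = "psd", band = band_names[b], region = r
      )
    }
  }
  feature_table(do.call(cbind, cols), dplyr::bind_rows(meta))
}

#' Spectral power ratios per region
#'
#' The 16 ratios of linear (non-logged) band powers listed by
#' [psd_ratio_scheme()], computed in every region: 16 x 15 = 240 columns on
#' the standard montage.
#'
#' @param psd A [feature_table()] of `psd` columns covering all five bands
#'   in every region.
#' @return A [feature_table()] of `psd_ratio` columns named
#'   `ratio_<name>_<region>`; the band metadata holds the numerator band.
#' @export
compute_psd_ratios <- function(psd) {
  meta <- feature_meta(psd)
  if (!all(meta$kind == "psd")) abort("input must contain only psd columns")
  vals <- ft_values(psd)
  if (any(vals <= 0)) abort("band powers must be strictly positive")
  regions <- unique(meta$region)
  scheme <- psd_ratio_scheme()
  band_col <- function(b, r) {
    j <- which(meta$band == b & meta$region == r)
    if (length(j) != 1) {
      abort(sprintf("missing psd column for band %s region %s", b, r))
    }
    vals[, j]
  }
  cols <- list()
  out_meta <- list()
  for (i in seq_len(nrow(scheme))) {
    for (r in regions) {
      den <- Reduce(`+`, lapply(scheme$den[[i]], band_col, r = r))
      cols[[length(cols) + 1L]] <- band_col(scheme$num[i], r) / den
      out_meta[[length(out_meta) + 1L]] <- tibble::tibble(
        feature = paste("ratio", scheme$ratio[i], r, sep = "_"),
        kind = "psd_ratio", band = scheme$num[i], region = r
      )
    }
  }
  feature_table(do.call(cbind, cols), dplyr::bind_rows(out_meta))
}
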