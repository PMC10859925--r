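#' Frequency bands used for spectral averaging
#'
#' The five conventional EEG bands over which per-epoch spectra are averaged:
#' delta \[0.9, 4), theta \[4, 8), alpha \[8, 14), beta \[14, 25) and gamma
#' \[25, 40\] Hz. Intervals are half-open on the right except gamma, which is
#' closed at 40 Hz, so every frequency bin in 0.9--40 Hz belongs to exactly
#' one band.
#'
#' @param bands Optional named list of `c(low, high)` numeric pairs (Hz)
#'   replacing the default scheme. Must be ordered and non-overlapping.
#' @return A tibble with columns `band`, `low`, `high` and class
#'   `band_scheme`.
#' @examples
#' band_scheme()
#' @export
band_scheme <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- list(
      delta = c(0.9, 4), theta = c(4, 8), alpha = c(8, 14),
      beta = c(14, 25), gamma = c(25, 40)
    )
  }
  if (is.null(names(bands)) || any(!nzchar(names(bands)))) {
    abort("every band must be named")
  }
  tb <- tibble::tibble(
    band = names(bands),
    low = vapply(bands, `[`, numeric(1), 1L),
    high = vapply(bands, `[`, numeric(1), 2L)
  )
  if (any(tb$high <= tb$low)) abort("band high edge must exceed low edge")
  if (is.unsorted(tb$low, strictly = TRUE) ||
      any(tb$low[-1] < tb$high[-nrow(tb)])) {
    abort("bands must be ordered and non-overlapping")
  }
  class(tb) <- c("band_scheme", class(tb))
  tb
}

# frequency-bin membership: [low, high) everywhere, last band closed above
band_of_freq <- function(freqs, bands) {
  out <- rep(NA_character_, length(freqs))
  for (i in seq_len(nrow(bands))) {
    hit <- freqs >= bands$low[i] &
      (if (i == nrow(bands)) freqs <= bands$high[i] else freqs < bands$high[i])
    out[hit] <- bands$band[i]
  }
  out
}

#' Spatial regions of interest for the standard 38-channel montage
#'
#' `roi_map_15()` returns the 15-region grouping of the 38 analysis channels
#' of a 10--20 montage (ear electrodes A1/A2 excluded) used throughout the
#' analysis. `roi_map_9()` is the coarser display variant that merges the
#' left/midline/right central, parietal and occipital regions.
#'
#' @return A tibble with columns `region` and `channel`, class `roi_map`.
#' @examples
#' dplyr::count(roi_map_15(), region)
#' @export
roi_map_15 <- function() {
  regions <- list(
    pre_frontal     = c("Fp1", "Fp2", "Fpz"),
    left_frontal    = c("F3", "F7", "FC3", "FT7"),
    midline_frontal = c("Fz", "FCz"),
    right_frontal   = c("F4", "F8", "FC4", "FT8"),
    left_central    = c("C3", "CP3"),
    midline_central = c("Cz", "CPz"),
    right_central   = c("C4", "CP4"),
    left_temporal   = c("T3", "T5", "TP7"),
    right_temporal  = c("T4", "T6", "TP8"),
    left_parietal   = c("P3", "P5"),
    midline_parietal = "Pz",
    right_parietal  = c("P4", "P6"),
    left_occipital  = c("PO3", "PO7", "O1"),
    midline_occipital = c("POz", "Oz"),
    right_occipital = c("PO4", "PO8", "O2")
  )
  roi_map(regions)
}

#' @rdname roi_map_15
#' @export
roi_map_9 <- function() {
  m <- roi_map_15()
  merge_to <- c(
    left_central = "central", midline_central = "central",
    right_central = "central",
    left_parietal = "parietal", midline_parietal = "parietal",
    right_parietal = "parietal",
    left_occipital = "occipital", midline_occipital = "occipital",
    right_occipital = "occipital"
  )
  m$region <- ifelse(m$region %in% names(merge_to),
                     merge_to[m$region], m$region)
  m <- dplyr::distinct(m)
  class(m) <- c("roi_map", class(tibble::tibble()))
  m
}

#' Build a region-of-interest map from a named list
#'
#' @param regions Named list mapping region name to a character vector of
#'   channel names.
#' @return A `roi_map` tibble (columns `region`, `channel`).
#' @export
roi_map <- function(regions) {
  if (is.null(names(regions))) abort("regions must be a named list")
  tb <- tibble::tibble(
    region = rep(names(regions), lengths(regions)),
    channel = unlist(regions, use.names = FALSE)
  )
  if (anyDuplicated(tb)) abort("duplicated region/channel rows")
  class(tb) <- c("roi_map", class(tb))
  tb
}

# checks every recording channel is covered and every ROI has >=1 channel
check_roi_coverage <- function(rois, channel_names) {
  missing <- setdiff(channel_names, rois$channel)
  if (length(missing) > 0) {
    abort(paste0("channels not assigned to any region: ",
                 paste(missing, collapse = ", ")))
  }
  empty <- setdiff(unique(rois$region), rois$region[rois$channel %in% channel_names])
  if (length(empty) > 0) {
    abort(paste0("regions with no channels in the recording: ",
                 paste(empty, collapse = ", ")))
  }
  invisible(rois)
}

#' Names of the 38 analysis channels of the standard montage
#'
#' @return Character vector of channel labels, in region order.
#' @export
standard_channels <- function() roi_map_15()$channel

#' The 16 spectral power ratios computed per region
#'
#' Each ratio is a quotient of linear (non-logged) band powers; compound
#' denominators are sums of band powers.
#'
#' @return A tibble with columns `ratio`, `num` (numerator band) and `den`
#'   (list-column of denominator bands).
#' @export
psd_ratio_scheme <- function() {
  defs <- list(
    theta_delta = list("theta", "delta"),
    alpha_delta = list("alpha", "delta"),
    alpha_theta = list("alpha", "theta"),
    alpha_delta_theta = list("alpha", c("delta", "theta")),
    beta_delta = list("beta", "delta"),
    beta_theta = list("beta", "theta"),
    beta_alpha = list("beta", "alpha"),
    beta_delta_theta = list("beta", c("delta", "theta")),
    beta_theta_alpha = list("beta", c("theta", "alpha")),
    gamma_delta = list("gamma", "delta"),
    gamma_theta = list("gamma", "theta"),
    gamma_alpha = list("gamma", "alpha"),
    gamma_beta = list("gamma", "beta"),
    gamma_delta_theta = list("gamma", c("delta", "theta")),
    gamma_theta_alpha = list("gamma", c("theta", "alpha")),
    gamma_alpha_beta = list("gamma", c("alpha", "beta"))
  )
  tibble::tibble(
    ratio = names(defs),
    num = vapply(defs, function(d) d[[1]], character(1)),
    den = lapply(defs, function(d) d[[2]])
  )
}
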