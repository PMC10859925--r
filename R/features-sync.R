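#' Configuration of the synchrony features
#'
#' @param thresholds Connectivity-index thresholds `P` (each in (0, 1)).
#' @param window_epochs Odd number of adjacent epochs in the sliding
#'   cross-spectral window (default 5, i.e. 5 s at 1-s epochs).
#' @param nw,n_tapers Multitaper parameters for the per-epoch spectra.
#' @return A list of class `sync_config`.
#' @export
sync_config <- function(thresholds = c(0.6, 0.7, 0.8), window_epochs = 5,
                        nw = 4, n_tapers = 2 * nw - 1) {
  if (any(thresholds <= 0 | thresholds >= 1)) {
    abort("thresholds must lie strictly between 0 and 1")
  }
  if (window_epochs %% 2 != 1 || window_epochs < 1) {
    abort("window_epochs must be odd and positive")
  }
  structure(list(thresholds = thresholds, window_epochs = window_epochs,
                 nw = nw, n_tapers = n_tapers), class = "sync_config")
}

# per-epoch complex eigenspectra restricted to in-band bins:
# list(spec = array [n_bins, n_ch, k, n_epochs], freqs, band_of_bin)
sync_spectra <- function(epochs, bands, cfg) {
  d <- dim(epochs$data)
  if (d[1] < 1) abort("need at least one epoch")
  if (d[3] <= cfg$n_tapers) abort("epoch shorter than the taper support")
  tp <- dpss_tapers(d[3], nw = cfg$nw, k = cfg$n_tapers)
  freqs <- (seq_len(d[3] %/% 2 + 1) - 1) * epochs$sfreq / d[3]
  fb <- band_of_freq(freqs, bands)
  bins <- which(!is.na(fb))
  spec <- array(complex(real = 0), dim = c(length(bins), d[2],
                                           cfg$n_tapers, d[1]))
  for (e in seq_len(d[1])) {
    s <- epoch_eigenspectra(epochs$data[e, , , drop = TRUE], tp)
    spec[, , , e] <- s[bins, , , drop = FALSE]
  }
  list(spec = spec, freqs = freqs[bins], band_of_bin = fb[bins])
}

# sliding-window running sum along the last (epoch) dimension; at record
# edges the window is clamped to full length (shifted inward) rather than
# truncated, so every epoch's estimate pools the same number of segments
# — a truncated window would inflate coherence/PLV at the edges
window_sum <- function(m, half) {
  n <- ncol(m)
  cs <- cbind(0, t(apply(m, 1, cumsum)))
  idx <- window_bounds(n, half)
  cs[, idx$hi + 1L, drop = FALSE] - cs[, idx$lo, drop = FALSE]
}

window_bounds <- function(n, half) {
  w <- min(2L * half + 1L, n)
  lo <- pmax(1L, pmin(seq_len(n) - half, n - w + 1L))
  list(lo = lo, hi = lo + w - 1L)
}

window_count <- function(n, half) {
  idx <- window_bounds(n, half)
  idx$hi - idx$lo + 1L
}

#' Sliding-window coherence or phase-locking value per channel pair
#'
#' Cross-spectral densities are built from per-epoch multitaper spectra
#' averaged over a window of `window_epochs` adjacent epochs centred on the
#' current one (truncated at record edges). Coherence is
#' `|mean CSD|^2 / (mean PSD_x * mean PSD_y)` per frequency bin, averaged
#' within each band; the PLV averages the unit-normalised per-taper
#' cross-spectrum before taking the modulus. Both lie in \[0, 1\]. With 38
#' channels this yields 5 x 703 = 3,515 columns per measure.
#'
#' @param epochs An `epoched_recording`.
#' @param bands A [band_scheme()].
#' @param cfg A [sync_config()].
#' @param measure `"coherence"`, `"plv"`, or `"both"`.
#' @return A [feature_table()] (or named list of two when
#'   `measure = "both"`) with columns `<measure>_<band>_<chx>.<chy>` and
#'   pair metadata `"chx|chy"`.
#' @export
compute_pairwise_sync <- function(epochs, bands = band_scheme(),
                                  cfg = sync_config(),
                                  measure = c("both", "coherence", "plv")) {
  measure <- match.arg(measure)
  sp <- sync_spectra(epochs, bands, cfg)
  res <- pairwise_sync_from_spectra(sp, epochs$channel_names, cfg,
                                    bands$band)
  switch(measure, both = res, coherence = res$coherence, plv = res$plv)
}

pairwise_sync_from_spectra <- function(sp, channel_names, cfg, band_names) {
  dims <- dim(sp$spec)
  n_bins <- dims[1]; nch <- dims[2]; k <- dims[3]; ne <- dims[4]
  if (nch < 2) abort("need at least two channels")
  half <- (cfg$window_epochs - 1L) %/% 2L
  pair_idx <- utils::combn(nch, 2)
  np <- ncol(pair_idx)
  ix <- pair_idx[1, ]; iy <- pair_idx[2, ]
  wc <- window_count(ne, half)
  band_ids <- match(sp$band_of_bin, band_names)
  nb <- length(band_names)
  coh_acc <- array(0, dim = c(ne, np, nb))
  plv_acc <- array(0, dim = c(ne, np, nb))
  bin_n <- tabulate(band_ids, nbins = nb)
  for (f in seq_len(n_bins)) {
    csd <- matrix(complex(real = 0), np, ne)
    plvs <- matrix(complex(real = 0), np, ne)
    psd <- matrix(0, nch, ne)
    for (t in seq_len(k)) {
      v <- matrix(sp$spec[f, , t, ], nch, ne)
      psd <- psd + Re(v * Conj(v))
      cross <- v[ix, , drop = FALSE] * Conj(v[iy, , drop = FALSE])
      csd <- csd + cross
      mod <- Mod(cross)
      mod[mod == 0] <- 1
      plvs <- plvs + cross / mod
    }
    if (any(rowSums(psd) == 0)) {
      abort("silent channel (zero in-band power) in the recording")
    }
    # window-aggregate along epochs; counts cancel inside the coherence
    csd_w <- window_sum(Re(csd), half) + 1i * window_sum(Im(csd), half)
    psd_w <- window_sum(psd, half)
    denom <- psd_w[ix, , drop = FALSE] * psd_w[iy, , drop = FALSE]
    coh_f <- Mod(csd_w)^2 / denom
    plv_w <- window_sum(Re(plvs), half) + 1i * window_sum(Im(plvs), half)
    plv_f <- Mod(plv_w) / rep(wc * k, each = np)
    b <- band_ids[f]
    coh_acc[, , b] <- coh_acc[, , b] + t(coh_f)
    plv_acc[, , b] <- plv_acc[, , b] + t(plv_f)
  }
  pair_lab <- paste(channel_names[ix], channel_names[iy], sep = "|")
  build <- function(acc, kind) {
    cols <- list(); meta <- list()
    for (b in seq_len(nb)) {
      m <- acc[, , b] / bin_n[b]
      cols[[b]] <- m
      meta[[b]] <- tibble::tibble(
        feature = paste(kind, band_names[b],
                        gsub("|", ".", pair_lab, fixed = TRUE), sep = "_"),
        kind = kind, band = band_names[b], pair = pair_lab
      )
    }
    feature_table(do.call(cbind, cols), dplyr::bind_rows(meta))
  }
  list(coherence = build(coh_acc, "coherence"), plv = build(plv_acc, "plv"))
}

#' Thresholded connectivity-index features per region
#'
#' For every epoch, channel, band and threshold `P`, the index counts the
#' other channels whose synchrony with the channel is at least `P`; counts
#' are then channel-averaged within regions. With 3 thresholds, 5 bands and
#' 15 regions this yields 255 columns per measure.
#'
#' @param sync A pairwise [feature_table()] from [compute_pairwise_sync()]
#'   (single measure).
#' @param cfg A [sync_config()] (thresholds).
#' @param rois A [roi_map()].
#' @return A [feature_table()] of `coh_index`/`plv_index` columns named
#'   `<kind>_<band>_<region>_p<P>`.
#' @export
compute_connectivity_index <- function(sync, cfg = sync_config(),
                                       rois = roi_map_15()) {
  meta <- feature_meta(sync)
  kind_in <- unique(meta$kind)
  if (length(kind_in) != 1 || !kind_in %in% c("coherence", "plv")) {
    abort("sync table must hold a single pairwise measure")
  }
  out_kind <- if (kind_in == "coherence") "coh_index" else "plv_index"
  vals <- ft_values(sync)
  pairs <- strsplit(meta$pair, "|", fixed = TRUE)
  channels <- sort(unique(unlist(pairs)))
  check_roi_coverage(rois, channels)
  # every unordered channel pair must be present once per band
  expected <- choose(length(channels), 2)
  bands_in <- unique(meta$band)
  for (b in bands_in) {
    if (sum(meta$band == b) != expected) {
      abort(sprintf("band %s: expected %d channel pairs, found %d",
                    b, expected, sum(meta$band == b)))
    }
  }
  inc <- matrix(0, nrow(meta), length(channels),
                dimnames = list(NULL, channels))
  for (i in seq_along(pairs)) inc[i, pairs[[i]]] <- 1
  regions <- unique(rois$region)
  roi_mat <- vapply(regions, function(r) {
    w <- as.numeric(channels %in% rois$channel[rois$region == r])
    w / sum(w)
  }, numeric(length(channels)))
  cols <- list(); out_meta <- list()
  for (P in cfg$thresholds) {
    for (b in bands_in) {
      j <- which(meta$band == b)
      counts <- (vals[, j, drop = FALSE] >= P) %*% inc[j, , drop = FALSE]
      avg <- counts %*% roi_mat
      cols[[length(cols) + 1L]] <- avg
      out_meta[[length(out_meta) + 1L]] <- tibble::tibble(
        feature = paste0(out_kind, "_", b, "_", regions, "_p", P),
        kind = out_kind, band = b, region = regions, threshold = P
      )
    }
  }
  feature_table(do.call(cbind, cols), dplyr::bind_rows(out_meta))
}

#' Region-pair synchrony averages
#'
#' Per epoch, band and unordered region pair: the mean of the pairwise
#' synchrony over all cross-region channel pairs. With 15 regions and 5
#' bands this yields 525 columns per measure. These are descriptive
#' features; they are never fed to the SDA.
#'
#' @param sync A pairwise [feature_table()] (single measure).
#' @param rois A [roi_map()].
#' @return A [feature_table()] with columns
#'   `<kind>_<band>_<regionA>..<regionB>`.
#' @export
region_pair_features <- function(sync, rois = roi_map_15()) {
  meta <- feature_meta(sync)
  kind_in <- unique(meta$kind)
  if (length(kind_in) != 1) abort("sync table must hold a single measure")
  vals <- ft_values(sync)
  pairs <- strsplit(meta$pair, "|", fixed = TRUE)
  channels <- sort(unique(unlist(pairs)))
  check_roi_coverage(rois, channels)
  reg_of <- setNames(rois$region[match(channels, rois$channel)], channels)
  regions <- unique(rois$region)
  pr <- t(vapply(pairs, function(p) sort(unname(reg_of[p])), character(2)))
  cross <- pr[, 1] != pr[, 2]
  rp_label <- paste(pr[, 1], pr[, 2], sep = "..")
  cols <- list(); out_meta <- list()
  reg_pairs <- utils::combn(sort(regions), 2)
  for (b in unique(meta$band)) {
    for (i in seq_len(ncol(reg_pairs))) {
      lab <- paste(reg_pairs[1, i], reg_pairs[2, i], sep = "..")
      j <- which(meta$band == b & cross & rp_label == lab)
      if (length(j) == 0) {
        abort(sprintf("no channel pairs bridge regions %s", lab))
      }
      cols[[length(cols) + 1L]] <- rowMeans(vals[, j, drop = FALSE])
      out_meta[[length(out_meta) + 1L]] <- tibble::tibble(
        feature = paste(kind_in, b, lab, sep = "_"),
        kind = kind_in, band = b, pair = lab
      )
    }
  }
  feature_table(do.call(cbind, cols), dplyr::bind_rows(out_meta))
}

#' Compute the full feature set of a recording
#'
#' Runs the whole recipe: band/region powers, power ratios, pairwise
#' coherence and PLV, thresholded connectivity indices and region-pair
#' averages. On the standard 38-channel, 15-region montage the SDA input
#' has 75 + 240 + 255 + 255 = 825 columns and the analysis table
#' 825 + 525 + 525 = 1,875.
#'
#' @param epochs An `epoched_recording`.
#' @param bands A [band_scheme()].
#' @param rois A [roi_map()].
#' @param cfg A [sync_config()].
#' @return List with `sda_input`, `analysis`, `psd` and `pairwise` (list of
#'   the two channel-pair tables), all [feature_table()]s.
#' @export
compute_feature_set <- function(epochs, bands = band_scheme(),
                                rois = roi_map_15(), cfg = sync_config()) {
  psd <- compute_band_roi_psd(epochs, bands, rois, nw = cfg$nw,
                              n_tapers = cfg$n_tapers)
  ratios <- compute_psd_ratios(psd)
  pw <- compute_pairwise_sync(epochs, bands, cfg, measure = "both")
  coh_idx <- compute_connectivity_index(pw$coherence, cfg, rois)
  plv_idx <- compute_connectivity_index(pw$plv, cfg, rois)
  coh_rp <- region_pair_features(pw$coherence, rois)
  plv_rp <- region_pair_features(pw$plv, rois)
  sda_input <- ft_cbind(psd, ratios, coh_idx, plv_idx)
  list(
    sda_input = sda_input,
    analysis = ft_cbind(sda_input, coh_rp, plv_rp),
    psd = psd,
    pairwise = pw
  )
}
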