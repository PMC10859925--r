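# Shared fixtures: small montages, tiny simulated recordings, independent
# brute-force oracles, and a byte-level EDF writer (coded from the format
# definition, independently of the package reader).

small_rois <- function() {
  roi_map(list(front = c("c1", "c2"), back = c("c3", "c4")))
}

small_channels <- function() paste0("c", 1:4)

# piecewise recording on the 4-channel fixture montage at 100 Hz
small_recording <- function(states, seed = 1, sfreq = 100, noise_sd = 0.5) {
  generate_recording(
    sim_recipe(states, channels = small_channels(), sfreq = sfreq,
               rois = small_rois(), noise_sd = noise_sd),
    seed = seed
  )
}

# quick feature_table from a plain matrix
fake_feature_table <- function(vals, kind = "psd", band = "alpha",
                               region = "r1") {
  nf <- ncol(vals)
  feature_table(vals, tibble::tibble(
    feature = paste0("f", seq_len(nf)),
    kind = rep_len(kind, nf), band = rep_len(band, nf),
    region = rep_len(region, nf)
  ))
}

# ---- brute-force oracles -------------------------------------------------

# Ward distance as the literal increase in within-cluster sum of squares
bf_ward_distance <- function(a, b) {
  wss <- function(m) sum(sweep(m, 2, colMeans(m), "-")^2)
  wss(rbind(a, b)) - wss(a) - wss(b)
}

bf_silhouette_pair <- function(x, ia, ib) {
  d <- as.matrix(dist(x))
  lab <- rep(NA_integer_, nrow(x)); lab[ia] <- 1L; lab[ib] <- 2L
  s <- vapply(c(ia, ib), function(i) {
    own <- setdiff(which(lab == lab[i]), i)
    if (length(own) == 0) return(0)
    a <- mean(d[i, own])
    b <- mean(d[i, which(lab != lab[i])])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

bf_calinski_harabasz_pair <- function(x, ia, ib) {
  xa <- x[ia, , drop = FALSE]; xb <- x[ib, , drop = FALSE]
  n <- nrow(xa) + nrow(xb)
  mu <- colMeans(rbind(xa, xb))
  bss <- nrow(xa) * sum((colMeans(xa) - mu)^2) +
    nrow(xb) * sum((colMeans(xb) - mu)^2)
  wss <- sum(sweep(xa, 2, colMeans(xa), "-")^2) +
    sum(sweep(xb, 2, colMeans(xb), "-")^2)
  (bss / (2 - 1)) / (wss / (n - 2))
}

bf_davies_bouldin_pair <- function(x, ia, ib) {
  xa <- x[ia, , drop = FALSE]; xb <- x[ib, , drop = FALSE]
  sa <- mean(sqrt(rowSums(sweep(xa, 2, colMeans(xa), "-")^2)))
  sb <- mean(sqrt(rowSums(sweep(xb, 2, colMeans(xb), "-")^2)))
  (sa + sb) / sqrt(sum((colMeans(xa) - colMeans(xb))^2))
}

# ---- EDF fixture writer --------------------------------------------------

# writes a minimal continuous EDF: one data record per second, int16
# samples, physical = digital scaling chosen so values round-trip exactly
write_edf_fixture <- function(path, signal, sfreq, labels) {
  nch <- nrow(signal)
  spr <- as.integer(sfreq)
  n_rec <- ncol(signal) %/% spr
  stopifnot(ncol(signal) == n_rec * spr, all(signal == round(signal)),
            max(abs(signal)) <= 32767)
  pad <- function(s, w) formatC(s, width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("patient", 80), pad("recording", 80),
    pad("01.01.20", 8), pad("00.00.00", 8),
    pad(as.character(256 * (1 + nch)), 8), pad("", 44),
    pad(as.character(n_rec), 8), pad("1", 8), pad(as.character(nch), 4)
  )
  writeChar(hdr, con, eos = NULL)
  wfield <- function(vals, w) {
    for (v in vals) writeChar(pad(v, w), con, eos = NULL)
  }
  wfield(labels, 16)                      # labels
  wfield(rep("", nch), 80)                # transducer
  wfield(rep("uV", nch), 8)               # physical dimension
  wfield(rep("-32768", nch), 8)           # physical min
  wfield(rep("32767", nch), 8)            # physical max
  wfield(rep("-32768", nch), 8)           # digital min
  wfield(rep("32767", nch), 8)            # digital max
  wfield(rep("", nch), 80)                # prefiltering
  wfield(rep(as.character(spr), nch), 8)  # samples per record
  wfield(rep("", nch), 32)                # reserved
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(nch)) {
      writeBin(as.integer(signal[ch, cols]), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

# Shared end-to-end fixture for the acceptance suite: an eight-state
# recording with strong band-power/synchrony contrasts on the 4-channel
# fixture montage, pushed through the full pipeline once and cached.
.acceptance_env <- new.env(parent = emptyenv())

acceptance_fixture <- function() {
  if (!is.null(.acceptance_env$fx)) return(.acceptance_env$fx)
  # full 38-channel montage; the 100-Hz sampling rate keeps every band
  # below Nyquist while holding the fixture inside the test budget
  recipe <- contrast_recipe(sfreq = 100)
  sim <- generate_recording(recipe, seed = 2025L)
  ep <- epoch_signal(sim$recording, 1)
  fs <- compute_feature_set(ep)
  clean_psd <- reject_artifact_epochs(fs$psd)
  rejected <- rejected_epochs(clean_psd)
  keep <- setdiff(seq_len(nrow(fs$sda_input)), rejected + 1L)
  sda_input <- ft_subset_rows(fs$sda_input, keep)
  analysis <- ft_subset_rows(fs$analysis, keep)
  tr <- suppressWarnings(fit_feature_transform(sda_input, n_components = 15))
  x <- transform_features(sda_input, tr)
  # planted boundaries mapped into the retained-epoch index space
  truth_kept <- segment_partition(
    vapply(interior_boundaries_of(sim$truth), function(b) {
      sum(keep <= b)
    }, integer(1)),
    length(keep)
  )
  grid <- sda_grid(N = 2:15, K = c(20, 30, 40), L = c(0, 20),
                   N_max = c(10, 15), K_max = c(30, 40), N_KM = 2:12)
  res <- run_sda(x, grid, seed = 7L)
  .acceptance_env$fx <- list(
    sim = sim, epochs = ep, features = fs, keep = keep,
    sda_input = sda_input, analysis = analysis, x = x,
    truth = truth_kept, grid = grid, result = res
  )
  .acceptance_env$fx
}

interior_boundaries_of <- function(p) {
  b <- p$boundaries
  b[-c(1L, length(b))]
}
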