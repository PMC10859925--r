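# Feature engineering on a 4-channel / 2-region fixture montage at 100 Hz;
# the full-montage structural counts live in the acceptance suite.

make_epochs <- function(signal, sfreq = 100) {
  epoch_signal(continuous_recording(signal, sfreq, small_channels()), 1)
}

test_that("a pure 10-Hz tone concentrates power in the alpha band", {
  sfreq <- 100
  n <- sfreq * 12
  t <- seq_len(n) / sfreq
  sig <- matrix(rep(sin(2 * pi * 10 * t), 4), nrow = 4, byrow = TRUE) +
    matrix(rnorm(4 * n, sd = 0.01), 4)
  psd <- compute_band_roi_psd(make_epochs(sig), rois = small_rois())
  meta <- feature_meta(psd)
  expect_equal(nrow(meta), 5 * 2)        # 5 bands x 2 regions
  vals <- colMeans(as.matrix(as.data.frame(psd)))
  for (r in c("front", "back")) {
    by_band <- vals[meta$region == r]
    expect_equal(names(which.max(by_band)), paste0("psd_alpha_", r))
  }
})

test_that("white noise yields near-equal band-averaged power", {
  set.seed(7)
  sig <- matrix(rnorm(4 * 100 * 120), 4)   # 120 one-second epochs
  psd <- compute_band_roi_psd(make_epochs(sig), rois = small_rois())
  meta <- feature_meta(psd)
  vals <- colMeans(as.matrix(as.data.frame(psd)))
  front <- vals[meta$region == "front"]
  expect_lt(diff(range(front)) / mean(front), 0.15)
})

test_that("power ratios follow their definitions", {
  bands <- c("delta", "theta", "alpha", "beta", "gamma")
  meta <- tibble::tibble(feature = paste0("psd_", bands, "_r1"),
                         kind = "psd", band = bands, region = "r1")
  # delta=2, theta=4 -> theta/delta = 2
  psd <- feature_table(matrix(c(2, 4, 8, 16, 32), nrow = 1), meta)
  ratios <- compute_psd_ratios(psd)
  rmeta <- feature_meta(ratios)
  expect_equal(nrow(rmeta), 16)
  v <- as.numeric(as.data.frame(ratios))
  names(v) <- rmeta$feature
  expect_equal(unname(v["ratio_theta_delta_r1"]), 2)
  expect_equal(unname(v["ratio_gamma_delta_theta_r1"]), 32 / 6)

  # all bands equal c: single-band ratios 1, gamma/(alpha+beta) = 0.5
  psd2 <- feature_table(matrix(rep(3, 5), nrow = 1), meta)
  v2 <- as.numeric(as.data.frame(compute_psd_ratios(psd2)))
  names(v2) <- rmeta$feature
  expect_equal(unname(v2["ratio_theta_delta_r1"]), 1)
  expect_equal(unname(v2["ratio_gamma_alpha_beta_r1"]), 0.5)

  expect_error(compute_psd_ratios(
    feature_table(matrix(c(0, 4, 8, 16, 32), nrow = 1), meta)
  ), "positive")
})

test_that("a copied channel has coherence and PLV of 1 in every band", {
  set.seed(11)
  n <- 100 * 12
  base <- rnorm(n)
  sig <- rbind(base, base, rnorm(n), rnorm(n))
  sync <- compute_pairwise_sync(make_epochs(sig), cfg = sync_config(),
                                measure = "both")
  for (tab in sync) {
    meta <- feature_meta(tab)
    j <- meta$pair == "c1|c2"
    expect_true(all(abs(as.matrix(as.data.frame(tab))[, j] - 1) < 1e-9))
    expect_true(all(as.matrix(as.data.frame(tab)) >= 0))
    expect_true(all(as.matrix(as.data.frame(tab)) <= 1 + 1e-12))
  }
})

test_that("independent channels show only window-limited synchrony bias", {
  set.seed(13)
  sig <- matrix(rnorm(4 * 100 * 200), 4)   # 200 epochs
  sync <- compute_pairwise_sync(make_epochs(sig), measure = "coherence")
  vals <- as.matrix(as.data.frame(sync))
  # 5 epochs x 7 tapers ~ 35 segments: bias ~ 1/35 per bin; band averages
  # must stay well below structured-data levels
  expect_lt(mean(vals), 0.12)
  expect_gt(mean(vals), 0.0)
})

test_that("connectivity index counts partners above threshold", {
  # 3 channels, coherences (1,2)=0.8, (1,3)=0.5, (2,3)=0.75 at P=0.7
  rois <- roi_map(list(r1 = "c1", r2 = "c2", r3 = "c3"))
  meta <- tibble::tibble(
    feature = c("coherence_alpha_c1.c2", "coherence_alpha_c1.c3",
                "coherence_alpha_c2.c3"),
    kind = "coherence", band = "alpha",
    pair = c("c1|c2", "c1|c3", "c2|c3")
  )
  sync <- feature_table(matrix(c(0.8, 0.5, 0.75), nrow = 1), meta)
  idx <- compute_connectivity_index(sync, sync_config(thresholds = 0.7),
                                    rois = rois)
  v <- as.numeric(as.data.frame(idx))
  names(v) <- feature_meta(idx)$feature
  expect_equal(unname(v[c("coh_index_alpha_r1_p0.7",
                          "coh_index_alpha_r2_p0.7",
                          "coh_index_alpha_r3_p0.7")]), c(1, 2, 1))

  # threshold above every value zeroes the index
  idx9 <- compute_connectivity_index(sync, sync_config(thresholds = 0.9),
                                     rois = rois)
  expect_true(all(as.matrix(as.data.frame(idx9)) == 0))
})

test_that("connectivity index is monotone non-increasing in the threshold", {
  set.seed(17)
  rois <- small_rois()
  pairs <- combn(small_channels(), 2)
  meta <- tibble::tibble(
    feature = paste0("coherence_alpha_", pairs[1, ], ".", pairs[2, ]),
    kind = "coherence", band = "alpha",
    pair = paste(pairs[1, ], pairs[2, ], sep = "|")
  )
  for (rep in 1:5) {
    sync <- feature_table(matrix(runif(3 * 6), nrow = 3), meta)
    idx <- compute_connectivity_index(
      sync, sync_config(thresholds = c(0.3, 0.5, 0.7)), rois = rois
    )
    m <- feature_meta(idx)
    v <- as.matrix(as.data.frame(idx))
    for (r in unique(m$region)) {
      cols <- order(m$threshold[m$region == r])
      sub <- v[, which(m$region == r)[cols], drop = FALSE]
      expect_true(all(diff(t(sub)) <= 1e-12))
    }
  }
})

test_that("region-pair averages reduce to channel pairs for singleton regions", {
  rois <- roi_map(list(r1 = "c1", r2 = "c2"))
  meta <- tibble::tibble(feature = "coherence_alpha_c1.c2",
                         kind = "coherence", band = "alpha", pair = "c1|c2")
  sync <- feature_table(matrix(c(0.4, 0.6), ncol = 1), meta)
  rp <- region_pair_features(sync, rois)
  expect_equal(as.numeric(as.matrix(as.data.frame(rp))), c(0.4, 0.6))

  # constant pairwise values average to the same constant
  pairs <- combn(small_channels(), 2)
  meta4 <- tibble::tibble(
    feature = paste0("coherence_alpha_", pairs[1, ], ".", pairs[2, ]),
    kind = "coherence", band = "alpha",
    pair = paste(pairs[1, ], pairs[2, ], sep = "|")
  )
  sync4 <- feature_table(matrix(0.37, nrow = 2, ncol = 6), meta4)
  rp4 <- region_pair_features(sync4, small_rois())
  expect_true(all(abs(as.matrix(as.data.frame(rp4)) - 0.37) < 1e-12))
})

test_that("region averaging commutes with common signal rescaling", {
  set.seed(19)
  sig <- matrix(rnorm(4 * 100 * 10), 4)
  ep1 <- make_epochs(sig)
  ep2 <- make_epochs(5 * sig)
  psd1 <- as.matrix(as.data.frame(
    compute_band_roi_psd(ep1, rois = small_rois())))
  psd2 <- as.matrix(as.data.frame(
    compute_band_roi_psd(ep2, rois = small_rois())))
  expect_equal(psd2, 25 * psd1, tolerance = 1e-6)
  r1 <- compute_psd_ratios(compute_band_roi_psd(ep1, rois = small_rois()))
  r2 <- compute_psd_ratios(compute_band_roi_psd(ep2, rois = small_rois()))
  expect_equal(as.matrix(as.data.frame(r1)), as.matrix(as.data.frame(r2)),
               tolerance = 1e-6)
})

test_that("feature tables serialise to delimited text and back", {
  set.seed(23)
  ft <- fake_feature_table(matrix(rnorm(20), 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(as.matrix(as.data.frame(back)),
               as.matrix(as.data.frame(ft)), tolerance = 1e-12)
  expect_equal(feature_meta(back)$kind, feature_meta(ft)$kind)
})
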