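test_that("generated recordings honour the recipe and are seed-stable", {
  states <- list(
    state_spec(10, power_gain = c(alpha = 3)),
    state_spec(12, power_gain = c(delta = 2)),
    state_spec(8)
  )
  out1 <- small_recording(states, seed = 5)
  out2 <- small_recording(states, seed = 5)
  out3 <- small_recording(states, seed = 6)
  expect_identical(out1$recording$signal, out2$recording$signal)
  expect_false(identical(out1$recording$signal, out3$recording$signal))
  expect_equal(ncol(out1$recording$signal), 30 * 100)
  expect_equal(out1$truth$boundaries, c(0L, 10L, 22L, 30L))
  expect_error(state_spec(0), "duration")
  expect_error(state_spec(5, synchrony = c(alpha = 1.5)), "synchrony")
})

test_that("planted band gains are visible in the band-power readback", {
  states <- list(
    state_spec(20),
    state_spec(20, power_gain = c(alpha = 4)),
    state_spec(20)
  )
  out <- small_recording(states, seed = 7, noise_sd = 0.3)
  ep <- epoch_signal(out$recording, 1)
  psd <- compute_band_roi_psd(ep, rois = small_rois())
  meta <- feature_meta(psd)
  vals <- as.matrix(as.data.frame(psd))
  alpha_cols <- which(meta$band == "alpha")
  inside <- colMeans(vals[21:40, alpha_cols, drop = FALSE])
  outside <- colMeans(vals[c(1:20, 41:60), alpha_cols, drop = FALSE])
  expect_true(all(inside > 2 * outside))
})

test_that("synchrony levels drive the phase-locking readback", {
  states <- list(
    state_spec(25, synchrony = c(alpha = 0.95)),
    state_spec(25, synchrony = c(alpha = 0))
  )
  out <- small_recording(states, seed = 9, noise_sd = 0.2)
  ep <- epoch_signal(out$recording, 1)
  plv <- compute_pairwise_sync(ep, measure = "plv")
  meta <- feature_meta(plv)
  vals <- as.matrix(as.data.frame(plv))
  alpha_cols <- which(meta$band == "alpha")
  high <- mean(vals[1:25, alpha_cols])
  low <- mean(vals[26:50, alpha_cols])
  expect_gt(high, low + 0.2)
  expect_lt(low, 0.4)
})

test_that("surrogates permute rows without changing their multiset", {
  set.seed(179)
  ft <- fake_feature_table(matrix(rnorm(60 * 5), 60, 5))
  sur1 <- make_surrogate(ft, seed = 3)
  sur2 <- make_surrogate(ft, seed = 3)
  expect_identical(as.matrix(as.data.frame(sur1)),
                   as.matrix(as.data.frame(sur2)))
  v0 <- as.matrix(as.data.frame(ft))
  v1 <- as.matrix(as.data.frame(sur1))
  expect_false(identical(v0, v1))
  expect_equal(v0[order(v0[, 1]), ], v1[order(v1[, 1]), ],
               ignore_attr = TRUE)
  expect_equal(colMeans(v0), colMeans(v1))
  expect_equal(apply(v0, 2, sd), apply(v1, 2, sd))

  # epoched recordings shuffle with the same bookkeeping
  rec <- small_recording(list(state_spec(6), state_spec(6)), seed = 11)
  ep <- epoch_signal(rec$recording, 1)
  sur <- make_surrogate(ep, seed = 4)
  perm <- attr(sur, "permutation")
  expect_equal(sur$data[1, , ], ep$data[perm[1], , ])
  expect_equal(sur$epoch_index, ep$epoch_index[perm])
})

test_that("state rearrangement moves whole blocks and predicts boundaries", {
  set.seed(181)
  x <- matrix(rnorm(50 * 3), 50, 3)
  p <- segment_partition(c(10, 25), 50)
  out <- rearrange_states(x, p, seed = 21)
  expect_equal(sort(diff(out$expected$boundaries)),
               sort(diff(p$boundaries)))
  blocks <- list(1:10, 11:25, 26:50)
  expect_identical(out$data, x[unlist(blocks[out$state_order]), ])

  # a single-state partition can only map to itself
  p1 <- segment_partition(integer(0), 50)
  out1 <- rearrange_states(x, p1, seed = 22)
  expect_identical(out1$data, x)
  expect_identical(out1$expected$boundaries, p1$boundaries)
})
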