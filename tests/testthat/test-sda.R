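test_that("ward and centroid distances match their definitions", {
  s1 <- cluster_summary(matrix(0, 1, 1))
  expect_equal(ward_distance(s1, s1), 0)
  expect_equal(centroid_distance(s1, s1), 0)

  a <- cluster_summary(matrix(0, 1, 1))
  b <- cluster_summary(matrix(2, 1, 1))
  expect_equal(ward_distance(a, b), 2)   # (1/2) * 4

  A <- matrix(c(0, 2), 2, 1)
  B <- matrix(c(6, 8), 2, 1)
  expect_equal(ward_distance(cluster_summary(A), cluster_summary(B)), 36)
  expect_equal(centroid_distance(cluster_summary(A), cluster_summary(B)), 6)

  expect_error(centroid_distance(cluster_summary(matrix(0, 1, 2)),
                                 cluster_summary(matrix(0, 1, 3))),
               "dimension")
})

test_that("ward distance equals the within-variance increase (brute force)", {
  set.seed(61)
  for (i in 1:10) {
    A <- matrix(rnorm(sample(2:8, 1) * 3), ncol = 3)
    B <- matrix(rnorm(sample(2:8, 1) * 3), ncol = 3)
    expect_equal(ward_distance(cluster_summary(A), cluster_summary(B)),
                 bf_ward_distance(A, B), tolerance = 1e-10)
  }
})

test_that("two temporally separated blobs split exactly at the change point", {
  set.seed(67)
  x <- rbind(matrix(rnorm(50 * 2, mean = 0), 50, 2),
             matrix(rnorm(50 * 2, mean = 6), 50, 2))
  labels <- ward_connectivity_cluster(x, n_clusters = 2, k_neighbors = 20)
  expect_equal(length(unique(labels[1:50])), 1)
  expect_equal(length(unique(labels[51:100])), 1)
  expect_false(labels[50] == labels[51])
})

test_that("with K >= n the constrained agglomeration matches stock Ward", {
  set.seed(71)
  for (rep in 1:3) {
    x <- matrix(rnorm(80 * 4), 80, 4)
    hc <- stats::hclust(dist(x), method = "ward.D2")
    for (k in c(2, 4, 7)) {
      ours <- ward_connectivity_cluster(x, k, k_neighbors = 200)
      ref <- stats::cutree(hc, k)
      # identical partitions up to label names
      expect_equal(length(unique(paste(ours, ref))), k)
    }
  }
})

test_that("n_clusters = n gives singletons", {
  x <- matrix(rnorm(12 * 2), 12, 2)
  expect_equal(sort(ward_connectivity_cluster(x, 12, 3)), 1:12)
})

test_that("cluster extents become segment boundaries", {
  p <- clusters_to_segments(c(1, 1, 2, 2, 1, 1))
  expect_equal(p$boundaries, c(0L, 2L, 4L, 6L))

  # time-contiguous clusters: segments coincide with clusters
  p2 <- clusters_to_segments(rep(1:3, times = c(3, 4, 2)))
  expect_equal(p2$boundaries, c(0L, 3L, 7L, 9L))

  # interleaved labels produce a finer tiling than either cluster
  p3 <- clusters_to_segments(c(1, 2, 1, 2))
  expect_equal(p3$boundaries, c(0L, 1L, 3L, 4L))
})

test_that("short segments merge toward the Ward-nearest neighbour", {
  # segments [0,3) [3,4) [4,10); the middle point sits nearer the left
  x <- matrix(c(0, 0, 0, 0.5, 10, 10, 10, 10, 10, 10), ncol = 1)
  p <- segment_partition(c(3, 4), 10)
  merged <- merge_short_segments(p, x, min_len = 1)
  expect_equal(merged$boundaries, c(0L, 4L, 10L))
  # brute-force check that the left merge is indeed the cheaper one
  expect_lt(bf_ward_distance(x[1:3, , drop = FALSE], x[4, , drop = FALSE]),
            bf_ward_distance(x[4, , drop = FALSE], x[5:10, , drop = FALSE]))

  # L = 0 is a no-op
  expect_equal(merge_short_segments(p, x, 0)$boundaries, p$boundaries)

  # when everything is short the partition collapses
  p_all <- segment_partition(c(3, 6), 9)
  x9 <- matrix(rnorm(9), ncol = 1)
  expect_equal(n_states(merge_short_segments(p_all, x9, min_len = 5)), 1)
})

test_that("close segments merge until D_min exceeds W * D_avg", {
  # three 2-point segments with adjacent Ward distances 1 and 10
  m3 <- 1 + sqrt(10)
  x <- matrix(c(0, 0, 1, 1, m3, m3), ncol = 1)
  p <- segment_partition(c(2, 4), 6)
  out <- merge_close_segments(p, x, w = 0.3)
  # D_avg = 5.5: the 1-pair merges; the surviving pair has D_min = D_avg
  expect_equal(n_states(out), 2)
  expect_equal(out$boundaries, c(0L, 4L, 6L))

  # two segments only: D_min = D_avg, never merged for W < 1
  p2 <- segment_partition(3, 6)
  expect_equal(merge_close_segments(p2, x, 0.3)$boundaries, p2$boundaries)

  # equal adjacent distances: no merge
  xeq <- matrix(c(0, 0, 2, 2, 4, 4), ncol = 1)
  peq <- segment_partition(c(2, 4), 6)
  expect_equal(merge_close_segments(peq, xeq, 0.3)$boundaries,
               peq$boundaries)
})

test_that("phase 1 enumerates exactly |N| x |K| x |L| triples", {
  set.seed(73)
  x <- rbind(matrix(rnorm(40 * 3), 40, 3),
             matrix(rnorm(40 * 3, 5), 40, 3))
  g <- sda_grid(N = 2:3, K = 20, L = 0, N_max = 3, K_max = 20, N_KM = 2:3)
  ph <- sda_phase1(x, g)
  expect_equal(nrow(ph), 2)

  # planted change point at 40: all candidate arrays stay within K of it
  g2 <- sda_grid(N = 2:4, K = c(10, 20), L = c(0, 5), N_max = 4,
                 K_max = 20, N_KM = 2:3)
  ph2 <- sda_phase1(x, g2)
  expect_equal(nrow(ph2), 3 * 2 * 2)
  for (i in seq_len(nrow(ph2))) {
    b <- ph2$boundaries[[i]]
    expect_true(all(abs(b - 40) <= ph2$K[i] | b %in% c(0, 80)))
  }
})

test_that("joint candidate pooling preserves multiplicities", {
  ph <- tibble::tibble(
    N = c(2L, 3L), K = c(20L, 20L), L = c(0L, 0L),
    boundaries = list(c(10L, 50L), c(12L, 50L))
  )
  expect_equal(build_joint_candidates(ph, 3, 20, 0), c(10, 12, 50, 50))
  expect_equal(build_joint_candidates(ph, 2, 20, 0), c(10, 50))
  expect_error(build_joint_candidates(ph, 3, 20, 99), "empty")

  # multiplicity of an index = number of contributing triples holding it
  set.seed(79)
  ph2 <- tibble::tibble(
    N = rep(2:4, each = 2), K = rep(c(20L, 25L), 3), L = 0L,
    boundaries = replicate(6, sort(sample(1:99, 3)), simplify = FALSE)
  )
  pooled <- build_joint_candidates(ph2, 4, 25, 0)
  for (v in unique(pooled)) {
    expect_equal(sum(pooled == v),
                 sum(vapply(ph2$boundaries, function(b) v %in% b,
                            logical(1))))
  }
})

test_that("candidate clustering extracts rounded centers per type", {
  cand <- c(10L, 12L, 50L, 50L)
  expect_equal(cluster_candidates(cand, "kmeans", 2, "mode", 100), c(10, 50))
  expect_equal(cluster_candidates(cand, "kmeans", 2, "mean", 100), c(11, 50))
  expect_equal(cluster_candidates(cand, "kmeans", 2, "median", 100),
               c(11, 50))
  # all candidates identical: a single center whatever the type
  for (ct in c("mean", "median", "mode")) {
    expect_equal(cluster_candidates(rep(33L, 6), "dbscan", 0.02, ct, 100,
                                    min_samples = 3), 33)
  }
  # three distinct values support three centers
  expect_equal(cluster_candidates(cand, "kmeans", 3, "mean", 100),
               c(10, 12, 50))
  # more clusters than distinct values: configuration skipped
  expect_null(cluster_candidates(cand, "kmeans", 4, "mean", 100))
})

test_that("1-D DBSCAN separates dense index clumps and drops sparse noise", {
  cand <- c(rep(20L, 6), 21L, rep(70L, 5), 95L)
  b <- cluster_candidates(cand, "dbscan", 0.02, "mean", 100,
                          min_samples = 3)
  expect_equal(b, c(20, 70))
})

test_that("partition selection prefers the true boundaries by silhouette", {
  set.seed(83)
  mu <- c(0, 6, -6)
  lab <- rep(1:3, each = 50)
  x <- matrix(rnorm(150 * 2), 150, 2) + cbind(mu[lab], mu[lab])
  cands <- tibble::tibble(
    boundaries = list(c(50L, 100L), c(20L, 130L))
  )
  win <- select_partition(x, cands, 2)
  expect_equal(win$boundaries[[1]], c(50L, 100L))
  expect_gt(bf_silhouette_pair(x, 1:50, 51:100),
            bf_silhouette_pair(x, 1:20, 21:130))
})

test_that("run_sda is deterministic and recovers planted states", {
  set.seed(89)
  mu <- matrix(rnorm(4 * 6, sd = 4), 4)
  lab <- rep(1:4, times = c(35, 30, 40, 35))
  x <- mu[lab, ] + matrix(rnorm(140 * 6), 140, 6)
  g <- sda_grid(N = 2:8, K = c(10, 15, 20), L = c(0, 5), N_max = 8,
                K_max = 20, N_KM = 2:6)
  res1 <- run_sda(x, g, seed = 4)
  res2 <- run_sda(x, g, seed = 4)
  expect_identical(tidy(res1), tidy(res2))
  p4 <- sda_partition(res1, 4)
  expect_lte(boundary_deviation(p4, segment_partition(c(35, 65, 105), 140)),
             3)
  # every reported partition tiles the epoch range
  for (k in names(res1$by_n)) {
    p <- res1$by_n[[k]]$partition
    expect_equal(p$boundaries[1], 0L)
    expect_equal(p$boundaries[length(p$boundaries)], 140L)
    expect_true(all(diff(p$boundaries) > 0))
  }
  expect_error(run_sda(x[1:5, ], g), "epochs")
})
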