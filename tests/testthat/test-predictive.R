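make_power_table <- function(vals) {
  nf <- ncol(vals)
  feature_table(vals, tibble::tibble(
    feature = paste0("f", seq_len(nf)),
    kind = rep(c("psd", "psd_ratio"), length.out = nf),
    band = "alpha", region = "r"
  ))
}

test_that("synchrony features are excluded, power features kept", {
  kinds <- c(rep("psd", 3), rep("psd_ratio", 4), rep("coherence", 2),
             rep("plv_index", 2))
  ft <- feature_table(matrix(rnorm(11 * 10), 10, 11), tibble::tibble(
    feature = paste0("f", 1:11), kind = kinds, band = "alpha", region = "r"
  ))
  out <- exclude_sync_features(ft)
  expect_equal(ncol(out), 7)
  expect_setequal(unique(feature_meta(out)$kind), c("psd", "psd_ratio"))

  # a pure power table passes through unchanged
  pow <- make_power_table(matrix(rnorm(40), 10, 4))
  expect_equal(ncol(exclude_sync_features(pow)), 4)
})

test_that("well-separated states are classified almost perfectly", {
  set.seed(157)
  n <- 180
  lab <- rep(1:3, each = 60)
  mu <- matrix(c(0, 0, 6, 0, 0, 6), 3, 2, byrow = TRUE)
  vals <- cbind(mu[lab, ] + matrix(rnorm(n * 2, sd = 0.5), n, 2),
                matrix(rnorm(n * 6), n, 6))
  ft <- make_power_table(vals)
  p <- segment_partition(c(60, 120), n)
  proto <- classifier_protocol(n_components = 5)
  clf <- fit_state_classifiers(ft, p, proto, seed = 11)
  expect_gt(max(glance(clf)$accuracy), 0.95)
  expect_gt(max(glance(clf)$macro_f1), 0.95)
  expect_gt(min(dplyr::summarise(
    dplyr::group_by(tidy(clf), family),
    auc = mean(roc_auc))$auc), 0.95)
})

test_that("binary ROC AUC matches the closed-form two-Gaussian value", {
  set.seed(163)
  n <- 1600
  delta <- 1.5
  lab <- rep(1:2, each = n / 2)
  x1 <- c(rnorm(n / 2, delta), rnorm(n / 2, 0))
  vals <- cbind(x1, matrix(rnorm(n * 3, sd = 1), n, 3))
  ft <- make_power_table(vals)
  p <- segment_partition(n / 2, n)
  proto <- classifier_protocol(
    families = "logistic", n_components = 2,
    grids = list(logistic = expand.grid(alpha = 0, lambda = 0.01))
  )
  clf <- fit_state_classifiers(ft, p, proto, seed = 13)
  expected_auc <- pnorm(delta / sqrt(2))
  expect_equal(mean(tidy(clf)$roc_auc), expected_auc, tolerance = 0.04)
})

test_that("label-shuffled data sits at chance level across seeds", {
  set.seed(167)
  n <- 240
  vals <- matrix(rnorm(n * 10), n, 10)
  ft <- make_power_table(vals)
  p <- segment_partition(n / 2, n)
  proto <- classifier_protocol(
    families = "logistic", n_components = 5,
    grids = list(logistic = expand.grid(alpha = 0, lambda = 0.1))
  )
  ba <- vapply(1:20, function(s) {
    # on pure noise the IV filter legitimately finds nothing and warns
    clf <- suppressWarnings(fit_state_classifiers(ft, p, proto, seed = s))
    mean(tidy(clf)$balanced_accuracy)
  }, numeric(1))
  expect_lt(abs(mean(ba) - 0.5), 0.05)
})

test_that("fitting the filter and projection on all data leaks optimism", {
  set.seed(173)
  n <- 70
  vals <- matrix(rnorm(n * 150), n, 150)   # pure noise, many features
  ft <- make_power_table(vals)
  p <- segment_partition(n / 2, n)
  proto <- classifier_protocol(
    families = "logistic", n_components = 5,
    grids = list(logistic = expand.grid(alpha = 0, lambda = 0.1))
  )
  honest <- fit_state_classifiers(ft, p, proto, seed = 17)
  leaky <- fit_state_classifiers(ft, p, proto, seed = 17,
                                 .preprocess_on = "all")
  expect_gt(mean(tidy(leaky)$roc_auc), mean(tidy(honest)$roc_auc))
})

test_that("block splitting holds out the tail of every state", {
  n <- 100
  p <- segment_partition(50, n)
  ft <- make_power_table(matrix(rnorm(n * 6), n, 6))
  proto <- classifier_protocol(
    families = "logistic", split = "block", n_components = 3,
    grids = list(logistic = expand.grid(alpha = 0, lambda = 0.1))
  )
  # pure-noise features: the IV filter legitimately finds nothing
  clf <- suppressWarnings(fit_state_classifiers(ft, p, proto, seed = 19))
  expect_setequal(clf$split$test, c(31:50, 81:100))
})
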