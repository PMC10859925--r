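#' Two-cluster validity measures for a pair of adjacent states
#'
#' The two segments are treated as a two-cluster dataset and five measures
#' are computed on the feature rows: the mean Silhouette coefficient
#' (`s(i) = (b - a) / max(a, b)`; a point alone in its cluster scores 0),
#' the Calinski-Harabasz variance-ratio index with its two-cluster
#' degrees-of-freedom factors, the Davies-Bouldin index, and the Ward and
#' centroid inter-cluster distances.
#'
#' @param x Epochs x dims feature matrix.
#' @param idx_a,idx_b Row indices (1-based) of the two segments.
#' @return A one-row tibble with columns `silhouette`,
#'   `calinski_harabasz`, `davies_bouldin`, `ward_distance`,
#'   `centroid_distance`.
#' @export
pair_quality <- function(x, idx_a, idx_b) {
  x <- as.matrix(x)
  if (length(idx_a) < 1 || length(idx_b) < 1) {
    abort("both segments must be non-empty")
  }
  xa <- x[idx_a, , drop = FALSE]
  xb <- x[idx_b, , drop = FALSE]
  na <- nrow(xa); nb <- nrow(xb)
  mu_a <- colMeans(xa); mu_b <- colMeans(xb)

  dall <- as.matrix(stats::dist(rbind(xa, xb)))
  sel_a <- seq_len(na); sel_b <- na + seq_len(nb)
  cross <- dall[sel_a, sel_b, drop = FALSE]
  sil_one <- function(own, other_means, n_own) {
    if (n_own == 1) return(0)
    a <- rowSums(own) / (n_own - 1)
    s <- (other_means - a) / pmax(a, other_means)
    s[!is.finite(s)] <- 0
    s
  }
  da <- dall[sel_a, sel_a, drop = FALSE]
  db <- dall[sel_b, sel_b, drop = FALSE]
  s_a <- sil_one(da, rowMeans(cross), na)
  s_b <- sil_one(db, colMeans(cross), nb)
  silhouette <- mean(c(s_a, s_b))

  n <- na + nb
  mu <- (na * mu_a + nb * mu_b) / n
  bss <- na * sum((mu_a - mu)^2) + nb * sum((mu_b - mu)^2)
  wss <- sum(sweep(xa, 2, mu_a, "-")^2) + sum(sweep(xb, 2, mu_b, "-")^2)
  ch <- if (wss == 0) Inf else (bss / 1) / (wss / (n - 2))

  d_ab <- sqrt(sum((mu_a - mu_b)^2))
  sc_a <- mean(sqrt(rowSums(sweep(xa, 2, mu_a, "-")^2)))
  sc_b <- mean(sqrt(rowSums(sweep(xb, 2, mu_b, "-")^2)))
  dbi <- if (d_ab == 0) Inf else (sc_a + sc_b) / d_ab

  tibble::tibble(
    silhouette = silhouette,
    calinski_harabasz = ch,
    davies_bouldin = dbi,
    ward_distance = (na * nb / n) * d_ab^2,
    centroid_distance = d_ab
  )
}

#' State-adapted validity scores of a partition
#'
#' Every measure of [pair_quality()] is computed on each pair of
#' time-adjacent states and averaged (unweighted) over pairs. These
#' pair-averaged versions drive partition selection inside the SDA and the
#' surrogate-contrast reporting.
#'
#' @param x Epochs x dims feature matrix.
#' @param p A [segment_partition()] with at least two states.
#' @return A tibble: one row per adjacent pair (`pair`, `state_a`,
#'   `state_b`, measures) plus attribute `summary`, a one-row tibble of
#'   pair-averaged measures (see [state_adapted_summary()]).
#' @export
state_adapted_scores <- function(x, p) {
  if (n_states(p) < 2) abort("partition must have at least two states")
  b <- p$boundaries
  rows <- lapply(seq_len(n_states(p) - 1), function(i) {
    q <- pair_quality(x, (b[i] + 1):b[i + 1], (b[i + 1] + 1):b[i + 2])
    dplyr::bind_cols(
      tibble::tibble(pair = i, state_a = i, state_b = i + 1), q
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "summary") <- dplyr::summarise(
    out,
    dplyr::across(c("silhouette", "calinski_harabasz", "davies_bouldin",
                    "ward_distance", "centroid_distance"), mean)
  )
  out
}

#' Pair-averaged summary of [state_adapted_scores()]
#' @param scores Output of [state_adapted_scores()].
#' @return One-row tibble of the five pair-averaged measures.
#' @export
state_adapted_summary <- function(scores) attr(scores, "summary")

# fast path used inside partition selection: silhouette average only
state_adapted_silhouette <- function(x, boundaries, n_epochs) {
  b <- sort(unique(c(0L, boundaries, n_epochs)))
  if (length(b) < 3) return(NA_real_)
  mean(vapply(seq_len(length(b) - 2), function(i) {
    pair_quality(x, (b[i] + 1):b[i + 1],
                 (b[i + 1] + 1):b[i + 2])$silhouette
  }, numeric(1)))
}
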