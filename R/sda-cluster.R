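#' Ward and centroid distances between clusters
#'
#' The Ward distance is the increase in total within-cluster variance when
#' two clusters merge, `(n_a n_b / (n_a + n_b)) * ||mu_a - mu_b||^2`; the
#' centroid distance is `||mu_a - mu_b||`, independent of cluster sizes.
#'
#' @param a,b Cluster summaries: lists with `n` (size) and `mu` (centroid
#'   vector), e.g. from [cluster_summary()].
#' @return Nonnegative scalar.
#' @examples
#' a <- cluster_summary(matrix(c(0, 2), ncol = 1))
#' b <- cluster_summary(matrix(c(6, 8), ncol = 1))
#' ward_distance(a, b)     # 36
#' centroid_distance(a, b) # 6
#' @export
ward_distance <- function(a, b) {
  check_cluster_pair(a, b)
  (a$n * b$n / (a$n + b$n)) * sum((a$mu - b$mu)^2)
}

#' @rdname ward_distance
#' @export
centroid_distance <- function(a, b) {
  check_cluster_pair(a, b)
  sqrt(sum((a$mu - b$mu)^2))
}

check_cluster_pair <- function(a, b) {
  if (a$n < 1 || b$n < 1) abort("clusters must be non-empty")
  if (length(a$mu) != length(b$mu)) abort("centroid dimensions differ")
  invisible(NULL)
}

#' Summarise a set of points as a cluster
#' @param x Numeric matrix, members in rows.
#' @return List with `n` and centroid `mu`.
#' @export
cluster_summary <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1) abort("clusters must be non-empty")
  list(n = nrow(x), mu = colMeans(x))
}

#' Ward agglomeration under a temporal connectivity constraint
#'
#' Agglomerative clustering of the epoch sequence in which a merge is
#' admissible only between clusters joined by at least one graph edge;
#' epochs `i` and `j` are connected when `|i - j| <= K`. At each step the
#' admissible pair with the smallest Ward distance merges. With
#' `K >= n_epochs` this reduces to unconstrained Ward agglomeration.
#'
#' @param x Numeric matrix, epochs in rows (the reduced feature space).
#' @param n_clusters Number of clusters to return (`N >= 2`).
#' @param k_neighbors Temporal radius `K` of the connectivity graph, in
#'   epochs.
#' @return Integer vector of cluster labels (1-based, relabelled in order
#'   of first appearance).
#' @export
ward_connectivity_cluster <- function(x, n_clusters, k_neighbors) {
  cuts <- ward_connectivity_cuts(x, k_neighbors, levels = n_clusters)
  cuts[[as.character(n_clusters)]]
}

# One agglomeration run, labels recorded at every requested cluster count.
# Returns a named list: as.character(level) -> integer labels.
ward_connectivity_cuts <- function(x, k_neighbors, levels) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (any(levels < 1 | levels > n)) {
    abort("requested cluster counts must lie in [1, n_epochs]")
  }
  if (k_neighbors < 1) abort("k_neighbors must be >= 1")
  levels <- sort(unique(as.integer(levels)), decreasing = TRUE)
  labels <- seq_len(n)
  out <- list()
  if (levels[1] == n) out[[as.character(n)]] <- labels
  want <- setdiff(levels, n)
  if (length(want) == 0 && length(out) > 0) return(out)

  size <- rep(1, n)
  mu <- x
  active <- rep(TRUE, n)
  # connectivity: cluster pair admissible iff some member pair within K
  conn <- abs(outer(seq_len(n), seq_len(n), "-")) <= k_neighbors
  diag(conn) <- FALSE
  d2 <- as.matrix(stats::dist(x))^2
  dmat <- 0.5 * d2                     # ward distance between singletons
  dmat[!conn] <- Inf
  diag(dmat) <- Inf

  n_active <- n
  while (n_active > min(levels)) {
    idx <- which.min(dmat)
    if (!is.finite(dmat[idx])) {
      abort("connectivity graph disconnected before reaching the requested level")
    }
    j <- (idx - 1L) %/% n + 1L
    i <- (idx - 1L) %% n + 1L
    a <- min(i, j); b <- max(i, j)
    # merge b into a
    na <- size[a]; nb <- size[b]
    mu[a, ] <- (na * mu[a, ] + nb * mu[b, ]) / (na + nb)
    size[a] <- na + nb
    active[b] <- FALSE
    labels[labels == b] <- a
    conn[a, ] <- conn[a, ] | conn[b, ]
    conn[, a] <- conn[a, ]
    conn[a, a] <- FALSE
    dmat[b, ] <- Inf
    dmat[, b] <- Inf
    nb_ok <- which(active & conn[a, ])
    nb_ok <- nb_ok[nb_ok != a]
    if (length(nb_ok) > 0) {
      diff <- sweep(mu[nb_ok, , drop = FALSE], 2, mu[a, ], "-")
      dn <- (size[a] * size[nb_ok] / (size[a] + size[nb_ok])) *
        rowSums(diff^2)
      dmat[a, nb_ok] <- dn
      dmat[nb_ok, a] <- dn
    }
    dmat[a, !active | !conn[a, ]] <- Inf
    dmat[!active | !conn[, a], a] <- Inf
    n_active <- n_active - 1L
    if (n_active %in% levels) {
      out[[as.character(n_active)]] <- match(labels, unique(labels))
    }
  }
  out
}

#' Convert cluster labels to a time-continuous segment partition
#'
#' Each cluster contributes its leftmost member index and one past its
#' rightmost member as boundaries; the sorted, deduplicated boundary set
#' (plus 0 and `n_epochs`) tiles the epoch range into time-continuous
#' segments. Clusters that interleave in time therefore produce a finer
#' tiling than either cluster alone.
#'
#' @param labels Integer cluster labels over epochs `0..n-1` (vector
#'   position = epoch + 1).
#' @return A [segment_partition()].
#' @examples
#' clusters_to_segments(c(1, 1, 2, 2, 1, 1))  # segments [0,2) [2,4) [4,6)
#' @export
clusters_to_segments <- function(labels) {
  n <- length(labels)
  bounds <- unlist(lapply(split(seq_len(n), labels), function(ix) {
    c(min(ix) - 1L, max(ix))
  }))
  segment_partition(bounds, n_epochs = n)
}
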