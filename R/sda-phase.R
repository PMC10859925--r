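#' Hyperparameter grid of the state-detecting algorithm
#'
#' Defaults are the study grid: phase 1 varies the Ward cluster count `N`
#' in \[2, 20\], the connectivity radius `K` in \[20, 50\] epochs and the
#' minimum state length `L` in {0, 20, 40, 60}, with merge coefficient
#' `W = 0.3` (19 x 31 x 4 = 2,356 triples). Phase 2 pools candidates over
#' `N <= N_max`, `K <= K_max` at fixed `L`, clusters the pooled boundary
#' multiset with K-means (`N_KM` in \[2, 15\]) and DBSCAN (radius `E_DBS`
#' on the epoch index normalised by the record length), and extracts mean,
#' median and mode centers.
#'
#' @param N,K,L,W,N_max,K_max,N_KM,E_DBS,center_types Grid axes; see
#'   Details.
#' @param dbscan_min_samples DBSCAN core-point threshold.
#' @return A list of class `sda_grid`.
#' @export
sda_grid <- function(N = 2:20, K = 20:50, L = c(0, 20, 40, 60), W = 0.3,
                     N_max = c(10, 15, 20), K_max = c(35, 40, 45, 50),
                     N_KM = 2:15, E_DBS = c(0.02, 0.025, 0.03),
                     center_types = c("mean", "median", "mode"),
                     dbscan_min_samples = 5) {
  if (length(N) == 0 || length(K) == 0 || length(L) == 0) {
    abort("N, K and L ranges must be non-empty")
  }
  if (W <= 0 || W >= 1) abort("W must lie in (0, 1)")
  if (any(N_max > max(N))) abort("N_max must not exceed max(N)")
  if (any(K_max > max(K))) abort("K_max must not exceed max(K)")
  structure(list(N = as.integer(N), K = as.integer(K), L = as.integer(L),
                 W = W, N_max = as.integer(N_max),
                 K_max = as.integer(K_max), N_KM = as.integer(N_KM),
                 E_DBS = E_DBS, center_types = center_types,
                 dbscan_min_samples = dbscan_min_samples),
            class = "sda_grid")
}

#' @export
#' @method print sda_grid
print.sda_grid <- function(x, ...) {
  cat(sprintf("<sda_grid> phase 1: %d x %d x %d = %d triples; phase 2: %d subsets\n",
              length(x$N), length(x$K), length(x$L), n_phase1_triples(x),
              length(x$N_max) * length(x$K_max) * length(x$L)))
  invisible(x)
}

#' Number of phase-1 hyperparameter triples of a grid
#' @param grid An [sda_grid()].
#' @return `|N| * |K| * |L|`.
#' @export
n_phase1_triples <- function(grid) {
  length(grid$N) * length(grid$K) * length(grid$L)
}

#' Phase 1: boundary candidates over the hyperparameter ensemble
#'
#' For every triple `(N, K, L)`: connectivity-constrained Ward clustering
#' into `N` clusters, conversion of cluster extents to a time-continuous
#' segment partition, merging of short segments (`<= L` epochs) and of
#' adjacent segments closer than `W` times the average adjacent Ward
#' distance. One agglomeration per `K` serves every `N` cut.
#'
#' @param x Epochs x dims feature matrix (the reduced SDA input).
#' @param grid An [sda_grid()].
#' @return A tibble with columns `N`, `K`, `L` and list-column
#'   `boundaries` (interior candidate indices per triple).
#' @export
sda_phase1 <- function(x, grid = sda_grid()) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n <= max(grid$N)) abort("need more epochs than the largest N")
  if (n < min(grid$K)) abort("need at least min(K) epochs")
  rows <- vector("list", n_phase1_triples(grid))
  ri <- 0L
  for (k in grid$K) {
    cuts <- ward_connectivity_cuts(x, k, levels = grid$N)
    for (nn in grid$N) {
      segs0 <- clusters_to_segments(cuts[[as.character(nn)]])
      for (l in grid$L) {
        p <- merge_short_segments(segs0, x, l)
        p <- merge_close_segments(p, x, grid$W)
        ri <- ri + 1L
        rows[[ri]] <- tibble::tibble(
          N = nn, K = k, L = l,
          boundaries = list(interior_boundaries(p))
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Pool phase-1 candidates into a joint multiset
#'
#' Multiset union (duplicates preserved — multiplicity measures boundary
#' stability) of the candidate arrays of all triples with `N <= N_max` and
#' `K <= K_max` at fixed `L`.
#'
#' @param phase1 Output tibble of [sda_phase1()].
#' @param N_max,K_max,L Subset limits.
#' @return Sorted integer vector with repetitions.
#' @export
build_joint_candidates <- function(phase1, N_max, K_max, L) {
  sel <- phase1$N <= N_max & phase1$K <= K_max & phase1$L == L
  if (!any(sel)) abort("empty phase-1 subset")
  sort(unlist(phase1$boundaries[sel]))
}

# 1-D DBSCAN on sorted values: core points have >= min_samples neighbours
# (self included) within eps; clusters are chains of core points closer
# than eps, with non-core points attached to a cluster when within eps of
# one of its core points. Returns integer labels (0 = noise).
dbscan_1d <- function(v, eps, min_samples) {
  n <- length(v)
  ord <- order(v)
  s <- v[ord]
  counts <- vapply(seq_len(n), function(i) {
    sum(s >= s[i] - eps & s <= s[i] + eps)
  }, integer(1))
  core <- counts >= min_samples
  labels_s <- integer(n)
  cl <- 0L
  last_core_val <- NULL
  for (i in seq_len(n)) {
    if (!core[i]) next
    if (is.null(last_core_val) || s[i] - last_core_val > eps) cl <- cl + 1L
    labels_s[i] <- cl
    last_core_val <- s[i]
  }
  # border points: within eps of a core point
  core_idx <- which(core)
  if (length(core_idx) > 0) {
    for (i in which(!core)) {
      d <- abs(s[core_idx] - s[i])
      j <- which.min(d)
      if (d[j] <= eps) labels_s[i] <- labels_s[core_idx[j]]
    }
  }
  labels <- integer(n)
  labels[ord] <- labels_s
  labels
}

round_half_up <- function(x) floor(x + 0.5)

multiset_mode <- function(v) {
  tab <- table(v)
  as.numeric(names(tab)[which.max(tab)])   # ties -> smallest value
}

#' Cluster a pooled boundary multiset into final boundary candidates
#'
#' K-means (duplicates kept, so multiplicity acts as frequency weighting;
#' k-means++-style multi-start via `nstart`) or 1-D DBSCAN on indices
#' normalised by the record length. Per cluster the requested center type
#' is extracted and rounded half-up to an integer epoch; centers are
#' sorted and deduplicated, and degenerate boundaries (0 or `n_epochs`)
#' dropped.
#'
#' @param candidates Sorted integer multiset from
#'   [build_joint_candidates()].
#' @param method `"kmeans"` or `"dbscan"`.
#' @param param `N_KM` (kmeans) or `E_DBS` (dbscan).
#' @param center_type `"mean"`, `"median"` or `"mode"` (mode ties break to
#'   the smallest value).
#' @param n_epochs Record length (for DBSCAN normalisation and boundary
#'   validity).
#' @param min_samples DBSCAN core threshold.
#' @return Sorted integer vector of interior boundaries (possibly empty).
#' @export
cluster_candidates <- function(candidates,
                               method = c("kmeans", "dbscan"), param,
                               center_type = c("mean", "median", "mode"),
                               n_epochs, min_samples = 5) {
  method <- match.arg(method)
  center_type <- match.arg(center_type)
  if (length(candidates) == 0) return(integer(0))
  labels <- candidate_labels(candidates, method, param, n_epochs,
                             min_samples)
  if (is.null(labels)) return(NULL)
  centers_from_labels(candidates, labels, center_type, n_epochs)
}

# cluster assignment of the pooled multiset (0 = noise for DBSCAN)
candidate_labels <- function(candidates, method, param, n_epochs,
                             min_samples = 5) {
  if (method == "kmeans") {
    k <- as.integer(param)
    if (length(unique(candidates)) < k || length(candidates) < k) {
      return(NULL)
    }
    tryCatch(
      stats::kmeans(as.numeric(candidates), centers = k,
                    nstart = 10, iter.max = 100)$cluster,
      error = function(e) {
        # duplicate-heavy multisets can defeat random initialisation;
        # fall back to deterministic quantile seeding over unique values
        init <- unique(as.numeric(
          quantile(unique(candidates), probs = (seq_len(k) - 0.5) / k,
                   type = 1)
        ))
        if (length(init) < k) return(NULL)
        stats::kmeans(as.numeric(candidates), centers = init,
                      iter.max = 100)$cluster
      }
    )
  } else {
    dbscan_1d(candidates / n_epochs, eps = param,
              min_samples = min_samples)
  }
}

centers_from_labels <- function(candidates, labels, center_type,
                                n_epochs) {
  keep <- labels > 0
  if (!any(keep)) return(integer(0))
  centers <- vapply(split(candidates[keep], labels[keep]), function(v) {
    switch(center_type,
           mean = mean(v), median = median(v), mode = multiset_mode(v))
  }, numeric(1))
  b <- sort(unique(as.integer(round_half_up(centers))))
  b[b > 0 & b < n_epochs]
}

#' Select the best partition among candidate boundary lists
#'
#' Among all configurations whose deduplicated interior boundary count
#' equals `n_interior`, the partition with the maximum state-adapted
#' Silhouette wins; ties break to the first configuration in enumeration
#' order.
#'
#' @param x Epochs x dims feature matrix.
#' @param candidates Tibble with a `boundaries` list-column (configuration
#'   rows in canonical order).
#' @param n_interior Required number of interior boundaries.
#' @return The winning row joined with its silhouette, or NULL when no
#'   configuration matches.
#' @export
select_partition <- function(x, candidates, n_interior) {
  lens <- vapply(candidates$boundaries, length, integer(1))
  sel <- which(lens == n_interior)
  if (length(sel) == 0) return(NULL)
  n <- nrow(as.matrix(x))
  cache <- new.env(parent = emptyenv())
  sil <- vapply(sel, function(i) {
    key <- paste(candidates$boundaries[[i]], collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    v <- state_adapted_silhouette(x, candidates$boundaries[[i]], n)
    cache[[key]] <- v
    v
  }, numeric(1))
  best <- sel[which.max(sil)]
  out <- candidates[best, ]
  out$silhouette <- max(sil)
  out
}

#' Run the full state-detecting algorithm
#'
#' Phase 1 produces boundary candidates over the `(N, K, L)` ensemble;
#' phase 2 pools them per `(N_max, K_max, L)` subset, clusters the pooled
#' multiset (K-means and DBSCAN, three center types), and per target state
#' count keeps the partition with the best state-adapted Silhouette. The
#' algorithm reports every state count in `N_KM + 1` and deliberately does
#' not auto-select one: that choice is left to the analyst.
#'
#' @param x Epochs x dims reduced feature matrix (see
#'   [fit_feature_transform()]).
#' @param grid An [sda_grid()].
#' @param seed Integer seed controlling K-means restarts.
#' @return An `sda_result`: list with `by_n` (per state count: `partition`,
#'   `scores`, `summary`, `config`), `candidates` (all phase-2
#'   configuration rows), `phase1`, `grid`, `n_epochs`. Use [tidy()],
#'   [glance()] and [autoplot()] on it.
#' @export
run_sda <- function(x, grid = sda_grid(), seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  phase1 <- sda_phase1(x, grid)
  rows <- list()
  for (l in grid$L) {
    for (nm in grid$N_max) {
      for (km in grid$K_max) {
        cand <- build_joint_candidates(phase1, nm, km, l)
        # one clustering per (method, param); three center extractions
        configs <- rbind(
          data.frame(method = "kmeans", param = grid$N_KM),
          data.frame(method = "dbscan", param = grid$E_DBS)
        )
        for (ci in seq_len(nrow(configs))) {
          labels <- candidate_labels(cand, configs$method[ci],
                                     configs$param[ci], n,
                                     grid$dbscan_min_samples)
          if (is.null(labels)) next
          for (ct in grid$center_types) {
            b <- centers_from_labels(cand, labels, ct, n)
            if (length(b) == 0) next
            rows[[length(rows) + 1L]] <- tibble::tibble(
              N_max = nm, K_max = km, L = l,
              method = configs$method[ci], param = configs$param[ci],
              center_type = ct, boundaries = list(b)
            )
          }
        }
      }
    }
  }
  candidates <- dplyr::bind_rows(rows)
  by_n <- list()
  for (nkm in sort(unique(grid$N_KM))) {
    win <- select_partition(x, candidates, nkm)
    if (is.null(win)) next
    p <- segment_partition(win$boundaries[[1]], n)
    scores <- state_adapted_scores(x, p)
    by_n[[as.character(nkm + 1L)]] <- list(
      partition = p, scores = scores,
      summary = state_adapted_summary(scores),
      config = win[, c("N_max", "K_max", "L", "method", "param",
                       "center_type")]
    )
  }
  structure(list(by_n = by_n, candidates = candidates, phase1 = phase1,
                 grid = grid, n_epochs = n, seed = seed),
            class = "sda_result")
}

#' @export
#' @method print sda_result
print.sda_result <- function(x, ...) {
  cat(sprintf("<sda_result> %d epochs; partitions for %d state counts\n",
              x$n_epochs, length(x$by_n)))
  print(glance(x))
  invisible(x)
}

#' Tidy the partitions of an SDA run
#' @param x An `sda_result`.
#' @param ... Unused.
#' @return Tibble of state tables stacked over state counts
#'   (`n_states`, `state_id`, `start_epoch`, `end_epoch`, `duration_s`).
#' @export
tidy.sda_result <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$by_n), function(k) {
    dplyr::bind_cols(tibble::tibble(n_states = as.integer(k)),
                     tidy(x$by_n[[k]]$partition))
  }))
}

#' Per-state-count quality summary of an SDA run
#' @param x An `sda_result`.
#' @param ... Unused.
#' @return Tibble: one row per reported state count with the five
#'   pair-averaged measures and the winning configuration.
#' @export
glance.sda_result <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$by_n), function(k) {
    e <- x$by_n[[k]]
    dplyr::bind_cols(tibble::tibble(n_states = as.integer(k)),
                     e$summary, e$config)
  }))
}

#' Extract one partition from an SDA run
#' @param result An `sda_result`.
#' @param n_states Desired number of states.
#' @return A [segment_partition()].
#' @export
sda_partition <- function(result, n_states) {
  e <- result$by_n[[as.character(n_states)]]
  if (is.null(e)) {
    abort(sprintf("no partition reported for %d states", n_states))
  }
  e$partition
}
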