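#' Pairwise state comparisons over all features
#'
#' For every unordered pair of states and every feature, a two-sided
#' Mann-Whitney U test compares the feature's within-state distributions;
#' p-values are Bonferroni-corrected by the number of features (the
#' per-pair family). Each matrix entry is the percentage of features
#' significant at the corrected `alpha`. States with fewer than two epochs
#' are flagged untestable (NA row/column).
#'
#' Synchrony features are computed over sliding windows, so neighbouring
#' epochs are serially dependent; the tests are still run per the protocol
#' and the caveat is recorded in the returned object.
#'
#' @param features A [feature_table()].
#' @param p A [segment_partition()] over the same epochs.
#' @param alpha Corrected significance level (default 0.01).
#' @return List of class `state_test_matrix`: `matrix` (states x states,
#'   % significant, 0 diagonal), `n_features`, `alpha`, `caveats`.
#' @export
pairwise_state_tests <- function(features, p, alpha = 0.01) {
  vals <- ft_values(features)
  if (nrow(vals) != p$n_epochs) {
    abort("partition and feature table cover different epoch counts")
  }
  labels <- state_labels(p)
  ns <- n_states(p)
  nf <- ncol(vals)
  m <- matrix(0, ns, ns, dimnames = list(paste0("St", seq_len(ns)),
                                         paste0("St", seq_len(ns))))
  sizes <- tabulate(labels, nbins = ns)
  for (a in seq_len(ns - 1)) {
    for (b in (a + 1):ns) {
      if (sizes[a] < 2 || sizes[b] < 2) {
        m[a, b] <- m[b, a] <- NA_real_
        next
      }
      ia <- labels == a
      ib <- labels == b
      pv <- vapply(seq_len(nf), function(j) {
        suppressWarnings(
          wilcox.test(vals[ia, j], vals[ib, j], exact = FALSE)$p.value
        )
      }, numeric(1))
      pv[is.na(pv)] <- 1
      sig <- pmin(pv * nf, 1) < alpha
      m[a, b] <- m[b, a] <- 100 * mean(sig)
    }
  }
  structure(
    list(matrix = m, n_features = nf, alpha = alpha,
         caveats = "sliding-window synchrony features are serially dependent across adjacent epochs"),
    class = "state_test_matrix"
  )
}

#' @export
#' @method print state_test_matrix
print.state_test_matrix <- function(x, ...) {
  cat(sprintf("<state_test_matrix> %% features significant at corrected p < %g (Bonferroni x %d)\n",
              x$alpha, x$n_features))
  print(round(x$matrix, 1))
  invisible(x)
}

#' @rdname pairwise_state_tests
#' @param x A `state_test_matrix`.
#' @param ... Unused.
#' @export
tidy.state_test_matrix <- function(x, ...) {
  m <- x$matrix
  tibble::tibble(
    state_a = rep(seq_len(nrow(m)), ncol(m)),
    state_b = rep(seq_len(ncol(m)), each = nrow(m)),
    pct_significant = as.numeric(m)
  )
}

#' One-sample comparisons of each state against the recording median
#'
#' Per state and feature, a one-sample Wilcoxon signed-rank test of the
#' within-state values against the recording-wide median of that feature;
#' Bonferroni correction across features. When all within-state values
#' equal the median the p-value is 1 by convention (constant features are
#' never significant). Shares are reported overall and per band/kind
#' group.
#'
#' @inheritParams pairwise_state_tests
#' @return List of class `state_median_tests`: `by_state` tibble
#'   (`state`, `pct_significant`), `by_group` tibble, `alpha`,
#'   `n_features`.
#' @export
state_vs_median_tests <- function(features, p, alpha = 0.01) {
  vals <- ft_values(features)
  meta <- feature_meta(features)
  if (nrow(vals) != p$n_epochs) {
    abort("partition and feature table cover different epoch counts")
  }
  labels <- state_labels(p)
  ns <- n_states(p)
  nf <- ncol(vals)
  med <- apply(vals, 2, median)
  sig_tab <- list()
  for (s in seq_len(ns)) {
    ix <- labels == s
    pv <- vapply(seq_len(nf), function(j) {
      d <- vals[ix, j] - med[j]
      d <- d[d != 0]
      if (length(d) == 0) return(1)
      suppressWarnings(wilcox.test(d, exact = FALSE)$p.value)
    }, numeric(1))
    pv[is.na(pv)] <- 1
    sig_tab[[s]] <- tibble::tibble(
      state = s, feature = meta$feature, kind = meta$kind,
      band = meta$band, significant = pmin(pv * nf, 1) < alpha
    )
  }
  sig_tab <- dplyr::bind_rows(sig_tab)
  by_state <- sig_tab |>
    dplyr::group_by(state) |>
    dplyr::summarise(pct_significant = 100 * mean(significant))
  group_share <- function(key) {
    sig_tab |>
      dplyr::filter(!is.na(.data[[key]])) |>
      dplyr::group_by(state, group = .data[[key]]) |>
      dplyr::summarise(pct_significant = 100 * mean(significant),
                       .groups = "drop") |>
      dplyr::mutate(group_type = key, .before = group)
  }
  structure(
    list(by_state = by_state,
         by_group = dplyr::bind_rows(group_share("band"),
                                     group_share("kind")),
         alpha = alpha, n_features = nf),
    class = "state_median_tests"
  )
}

#' @export
#' @method print state_median_tests
print.state_median_tests <- function(x, ...) {
  cat(sprintf("<state_median_tests> corrected p < %g (Bonferroni x %d)\n",
              x$alpha, x$n_features))
  print(x$by_state)
  invisible(x)
}

utils::globalVariables("significant")
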