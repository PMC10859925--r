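#' Weight of evidence and information value of one feature
#'
#' The feature is cut into quantile bins on its pooled distribution. Per
#' bin, the share of events (epochs in the target state) and of
#' non-events is formed; `WoE = ln(event_share / nonevent_share)` and
#' `IV = sum((event_share - nonevent_share) * WoE)`. When any bin has a
#' zero count in either class, 0.5 is added to both class counts in every
#' bin (the usual smoothing convention); otherwise counts are used as
#' they stand. A constant feature yields a single degenerate bin and
#' `IV = 0`.
#'
#' The number of bins actually used is
#' `min(n_bins, max(2, floor(min(n_event, n_nonevent) / min_bin_events)))`
#' unless `adaptive = FALSE`: with few events per bin the WoE noise alone
#' drives IV past the interpretation thresholds, so bins are sized to
#' keep the expected occupancy of the rarer class adequate (about
#' `min_bin_events` of the rarer class per bin) — the standard
#' scoring-practice safeguard.
#'
#' @param x Numeric feature values, one per epoch.
#' @param event Logical vector: epoch belongs to the target state.
#' @param n_bins Maximum number of quantile bins (default 10).
#' @param min_bin_events Target expected count of the rarer class per bin
#'   used by the adaptive rule (default 10).
#' @param adaptive Set to `FALSE` to force exactly `n_bins` bins
#'   regardless of class sizes.
#' @return List with `table` (per-bin tibble: edges, counts, shares,
#'   `woe`, `iv_contribution`) and `iv` (scalar, >= 0).
#' @examples
#' woe_iv(c(rnorm(50), rnorm(50, 3)), rep(c(FALSE, TRUE), each = 50))$iv
#' @export
woe_iv <- function(x, event, n_bins = 10, min_bin_events = 10,
                   adaptive = TRUE) {
  event <- as.logical(event)
  if (!any(event) || all(event)) abort("both classes must be non-empty")
  if (length(x) != length(event)) abort("x and event lengths differ")
  if (adaptive) {
    rare <- min(sum(event), sum(!event))
    n_bins <- min(n_bins, max(2L, rare %/% min_bin_events))
  }
  edges <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(edges) < 2) {
    # constant feature: one degenerate bin, identical shares
    tab <- tibble::tibble(
      bin = 1L, lower = edges, upper = edges,
      n_event = sum(event), n_nonevent = sum(!event),
      event_share = 1, nonevent_share = 1, woe = 0, iv_contribution = 0
    )
    return(list(table = tab, iv = 0))
  }
  bins <- cut(x, breaks = edges, include.lowest = TRUE, labels = FALSE)
  nb <- length(edges) - 1
  n_ev <- tabulate(bins[event], nbins = nb)
  n_ne <- tabulate(bins[!event], nbins = nb)
  if (any(n_ev == 0) || any(n_ne == 0)) {
    n_ev <- n_ev + 0.5
    n_ne <- n_ne + 0.5
  }
  ev_share <- n_ev / sum(n_ev)
  ne_share <- n_ne / sum(n_ne)
  woe <- log(ev_share / ne_share)
  contrib <- (ev_share - ne_share) * woe
  tab <- tibble::tibble(
    bin = seq_len(nb), lower = edges[-length(edges)], upper = edges[-1],
    n_event = n_ev, n_nonevent = n_ne,
    event_share = ev_share, nonevent_share = ne_share,
    woe = woe, iv_contribution = contrib
  )
  list(table = tab, iv = sum(contrib))
}

#' Interpretation band of an information value
#'
#' `< 0.2` useless; `[0.2, 0.4)` weak; `[0.4, 0.6)` medium; `[0.6, 1]`
#' strong; `> 1` very strong / suspicious. These cut-offs are deliberately
#' higher than the credit-scoring convention because serially dependent
#' features inflate IV.
#'
#' @param iv Nonnegative information value(s).
#' @return Character vector of band labels.
#' @export
interpret_iv <- function(iv) {
  if (any(iv < 0)) abort("IV must be nonnegative")
  cut(iv, breaks = c(-Inf, 0.2, 0.4, 0.6, 1, Inf), right = FALSE,
      labels = c("useless", "weak", "medium", "strong",
                 "very strong/suspicious")) |>
    as.character() |>
    (\(lab) ifelse(iv == 1, "strong", lab))()
}

#' Information-value report for the states of a partition
#'
#' For each state, the state-membership indicator is the binary target and
#' the IV of every feature is computed. The report gives per-state
#' averages, the share of features at or above `threshold` (the
#' medium-or-better cut), and group breakdowns by frequency band and
#' feature kind.
#'
#' @param features A [feature_table()] (typically the full analysis set).
#' @param p A [segment_partition()] over the same epochs.
#' @param n_bins Quantile bins per feature (reduced with a warning when a
#'   state is smaller than `n_bins`).
#' @param threshold Reporting cut for "important" features (default 0.4).
#' @return List of class `iv_report`: `by_feature` (state x feature IVs),
#'   `by_state` (per-state summary incl. `pct_of_dataset`, `mean_iv`,
#'   `pct_iv_ge_threshold`), `by_group` (per state x group shares).
#' @export
iv_report <- function(features, p, n_bins = 10, threshold = 0.4) {
  vals <- ft_values(features)
  meta <- feature_meta(features)
  if (nrow(vals) != p$n_epochs) {
    abort("partition and feature table cover different epoch counts")
  }
  labels <- state_labels(p)
  ns <- n_states(p)
  by_feature <- list()
  for (s in seq_len(ns)) {
    event <- labels == s
    if (sum(event) < n_bins) {
      warn(sprintf("state %d has fewer epochs than n_bins; bins reduced",
                   s))
    }
    ivs <- vapply(seq_len(ncol(vals)), function(j) {
      woe_iv(vals[, j], event, n_bins = n_bins)$iv
    }, numeric(1))
    by_feature[[s]] <- tibble::tibble(
      state = s, feature = meta$feature, kind = meta$kind,
      band = meta$band, iv = ivs
    )
  }
  by_feature <- dplyr::bind_rows(by_feature)
  by_state <- by_feature |>
    dplyr::group_by(state) |>
    dplyr::summarise(
      mean_iv = mean(iv),
      pct_iv_ge_threshold = 100 * mean(iv >= threshold)
    ) |>
    dplyr::mutate(
      pct_of_dataset = 100 * diff(p$boundaries)[state] / p$n_epochs,
      .after = state
    )
  group_share <- function(key) {
    by_feature |>
      dplyr::filter(!is.na(.data[[key]])) |>
      dplyr::group_by(state, group = .data[[key]]) |>
      dplyr::summarise(
        pct_iv_ge_threshold = 100 * mean(iv >= threshold),
        .groups = "drop"
      ) |>
      dplyr::mutate(group_type = key, .before = group)
  }
  by_group <- dplyr::bind_rows(group_share("band"), group_share("kind"))
  structure(list(by_feature = by_feature, by_state = by_state,
                 by_group = by_group, threshold = threshold),
            class = "iv_report")
}

#' @export
#' @method print iv_report
print.iv_report <- function(x, ...) {
  cat(sprintf("<iv_report> %d states, %d features (threshold %.2f)\n",
              nrow(x$by_state), length(unique(x$by_feature$feature)),
              x$threshold))
  print(x$by_state)
  invisible(x)
}

#' @rdname iv_report
#' @param x An `iv_report`.
#' @param ... Unused.
#' @export
tidy.iv_report <- function(x, ...) x$by_feature

#' @rdname iv_report
#' @export
glance.iv_report <- function(x, ...) x$by_state
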