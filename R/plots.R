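#' Timeline plot of a segment partition
#'
#' @param p A [segment_partition()].
#' @param epoch_len_s Epoch length in seconds for the axis.
#' @return A ggplot object: coloured state blocks along the recording.
#' @export
plot_partition <- function(p, epoch_len_s = 1) {
  tab <- tidy(p, epoch_len_s = epoch_len_s)
  ggplot2::ggplot(tab) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start_epoch * epoch_len_s,
      xmax = .data$end_epoch * epoch_len_s,
      ymin = 0, ymax = 1, fill = factor(.data$state_id)
    ), colour = "black", linewidth = 0.2) +
    ggplot2::geom_text(ggplot2::aes(
      x = (.data$start_epoch + .data$end_epoch) / 2 * epoch_len_s,
      y = 0.5, label = .data$state_id
    )) +
    ggplot2::scale_fill_viridis_d(guide = "none") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("%d functional states", n_states(p))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @export
autoplot.segment_partition <- function(object, ...) {
  plot_partition(object, ...)
}

#' Plot an SDA run: state timeline and boundary-candidate density
#'
#' For one reported state count, the detected state blocks with the pooled
#' phase-2 boundary candidates of the winning configuration overlaid (dot
#' size = multiplicity), plus the per-adjacent-pair Silhouette polyline.
#'
#' @param object An `sda_result`.
#' @param n_states Which reported state count to draw (default: the one
#'   with the best state-adapted Silhouette).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sda_result <- function(object, n_states = NULL, ...) {
  gl <- glance(object)
  if (is.null(n_states)) {
    n_states <- gl$n_states[which.max(gl$silhouette)]
  }
  e <- object$by_n[[as.character(n_states)]]
  if (is.null(e)) abort("no partition for that state count")
  cand <- build_joint_candidates(object$phase1, e$config$N_max,
                                 e$config$K_max, e$config$L)
  cand_tab <- dplyr::count(tibble::tibble(boundary = cand), boundary)
  seg <- tidy(e$partition)
  pair_tab <- e$scores
  pair_x <- e$partition$boundaries[pair_tab$pair + 1]
  ggplot2::ggplot() +
    ggplot2::geom_rect(data = seg, ggplot2::aes(
      xmin = .data$start_epoch, xmax = .data$end_epoch,
      ymin = -0.1, ymax = 0, fill = factor(.data$state_id)
    ), colour = "black", linewidth = 0.2) +
    ggplot2::geom_point(data = cand_tab, ggplot2::aes(
      x = .data$boundary, y = 0.05, size = .data$n
    ), alpha = 0.4, colour = "grey30") +
    ggplot2::geom_line(
      data = tibble::tibble(x = pair_x, y = pair_tab$silhouette),
      ggplot2::aes(x = .data$x, y = .data$y),
      colour = "blue", linetype = "dashed"
    ) +
    ggplot2::geom_point(
      data = tibble::tibble(x = pair_x, y = pair_tab$silhouette),
      ggplot2::aes(x = .data$x, y = .data$y), colour = "blue"
    ) +
    ggplot2::scale_fill_viridis_d(guide = "none") +
    ggplot2::scale_size_area(name = "candidate\nmultiplicity") +
    ggplot2::labs(x = "epoch", y = "pair Silhouette",
                  title = sprintf("SDA partition into %d states", n_states)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a pairwise significance matrix
#' @param object A `state_test_matrix`.
#' @param ... Unused.
#' @return A ggplot tile plot of % significant features per state pair.
#' @export
autoplot.state_test_matrix <- function(object, ...) {
  tab <- tidy(object)
  ggplot2::ggplot(tab, ggplot2::aes(
    x = factor(.data$state_a), y = factor(.data$state_b),
    fill = .data$pct_significant
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = round(.data$pct_significant)
    ), size = 3) +
    ggplot2::scale_fill_viridis_c(name = "% significant") +
    ggplot2::labs(x = "state", y = "state") +
    ggplot2::theme_minimal()
}

#' Per-state information-value profile
#' @param object An `iv_report`.
#' @param ... Unused.
#' @return A ggplot bar chart: mean IV and share of important features.
#' @export
autoplot.iv_report <- function(object, ...) {
  tab <- object$by_state |>
    tidyr::pivot_longer(c("mean_iv", "pct_iv_ge_threshold"),
                        names_to = "measure")
  ggplot2::ggplot(tab, ggplot2::aes(
    x = factor(.data$state), y = .data$value
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "state", y = NULL) +
    ggplot2::theme_minimal()
}

#' ROC curves of the binary state classifiers
#' @param object A `state_classifiers` result.
#' @param ... Unused.
#' @return A ggplot of per-state ROC curves faceted by model family.
#' @export
autoplot.state_classifiers <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(
    x = .data$fpr, y = .data$tpr, colour = factor(.data$state)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = "state") +
    ggplot2::theme_minimal()
}
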