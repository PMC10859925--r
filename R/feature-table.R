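#' Epochs x features table with per-column metadata
#'
#' The analysis substrate: one row per retained epoch, one numeric column
#' per feature, with a metadata table describing each column (`feature`,
#' `kind`, `band`, `region`, `pair`, `threshold`). Kinds are `psd`,
#' `psd_ratio`, `coherence`, `plv`, `coh_index`, `plv_index`.
#'
#' @param values Numeric matrix (epochs x features) or data frame.
#' @param meta Tibble with one row per column of `values`; must contain
#'   `feature` and `kind`.
#' @return A tibble of class `feature_table` carrying the metadata in the
#'   `feature_meta` attribute.
#' @export
feature_table <- function(values, meta) {
  values <- as.matrix(values)
  if (anyNA(values)) abort("feature table must not contain NA")
  if (nrow(meta) != ncol(values)) {
    abort("meta must have one row per feature column")
  }
  if (!all(c("feature", "kind") %in% names(meta))) {
    abort("meta needs feature and kind columns")
  }
  for (col in c("band", "region", "pair")) {
    if (is.null(meta[[col]])) meta[[col]] <- NA_character_
  }
  if (is.null(meta[["threshold"]])) meta$threshold <- NA_real_
  if (anyDuplicated(meta$feature)) abort("duplicate feature names")
  colnames(values) <- meta$feature
  out <- tibble::as_tibble(values)
  attr(out, "feature_meta") <- tibble::as_tibble(meta)
  class(out) <- c("feature_table", class(out))
  out
}

#' Column metadata of a feature table
#' @param x A [feature_table()].
#' @return The metadata tibble (one row per feature column).
#' @export
feature_meta <- function(x) {
  m <- attr(x, "feature_meta")
  if (is.null(m)) abort("not a feature_table: missing feature_meta")
  m
}

ft_values <- function(x) {
  m <- as.matrix(as.data.frame(x))
  storage.mode(m) <- "double"
  m
}

#' Combine feature tables column-wise
#' @param ... `feature_table`s over the same epochs.
#' @return A single [feature_table()] with concatenated columns.
#' @export
ft_cbind <- function(...) {
  parts <- list(...)
  n <- unique(vapply(parts, nrow, integer(1)))
  if (length(n) != 1) abort("feature tables have differing epoch counts")
  feature_table(
    do.call(cbind, lapply(parts, ft_values)),
    dplyr::bind_rows(lapply(parts, feature_meta))
  )
}

#' Select feature columns by metadata
#' @param x A [feature_table()].
#' @param kinds Character vector of kinds to keep (NULL keeps all).
#' @param bands Character vector of bands to keep (NULL keeps all).
#' @return A [feature_table()] with the matching columns.
#' @export
ft_filter <- function(x, kinds = NULL, bands = NULL) {
  meta <- feature_meta(x)
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(kinds)) keep <- keep & meta$kind %in% kinds
  if (!is.null(bands)) keep <- keep & meta$band %in% bands
  if (!any(keep)) abort("no features match the filter")
  feature_table(ft_values(x)[, keep, drop = FALSE], meta[keep, ])
}

#' Subset the epochs (rows) of a feature table
#' @param x A [feature_table()].
#' @param keep Row index vector (1-based) of epochs to retain.
#' @return A [feature_table()] with the selected rows.
#' @export
ft_subset_rows <- function(x, keep) {
  feature_table(ft_values(x)[keep, , drop = FALSE], feature_meta(x))
}

#' Write / read a feature table as delimited text
#'
#' Values go to `<path>`; the column metadata goes to `<path>.meta.csv`.
#'
#' @param x A [feature_table()].
#' @param path Output CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the [feature_table()].
#' @export
write_feature_table <- function(x, path) {
  utils::write.csv(as.data.frame(ft_values(x)), path, row.names = FALSE)
  utils::write.csv(feature_meta(x), paste0(path, ".meta.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  vals <- utils::read.csv(path, check.names = FALSE)
  meta <- tibble::as_tibble(utils::read.csv(paste0(path, ".meta.csv")))
  feature_table(as.matrix(vals), meta)
}

#' @export
#' @method print feature_table
print.feature_table <- function(x, ...) {
  meta <- feature_meta(x)
  cat(sprintf("<feature_table> %d epochs x %d features (%s)\n",
              nrow(x), nrow(meta),
              paste(sprintf("%s: %d", names(table(meta$kind)),
                            as.integer(table(meta$kind))), collapse = ", ")))
  NextMethod()
}
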