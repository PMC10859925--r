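#' Reject artifact epochs by band-power outliers
#'
#' Single-pass rule: per power column, compute mean and SD over all epochs;
#' an epoch is rejected when any column deviates from its mean by more than
#' `sd_limit` standard deviations. Statistics come from the full
#' (uncleaned) table; columns with zero SD never flag anything. Remaining
#' epochs are reindexed contiguously.
#'
#' @param psd A [feature_table()] of raw (non-logged) `psd` columns.
#' @param sd_limit Deviation threshold in SDs (default 3).
#' @return The cleaned [feature_table()], with the 0-based original indices
#'   of rejected epochs in attribute `rejected_epochs` (see
#'   [rejected_epochs()]).
#' @export
reject_artifact_epochs <- function(psd, sd_limit = 3) {
  vals <- ft_values(psd)
  mu <- colMeans(vals)
  sdev <- apply(vals, 2, sd)
  dev <- abs(sweep(vals, 2, mu, "-"))
  lim <- sd_limit * sdev
  flag <- dev > rep(lim, each = nrow(vals))
  flag[, sdev == 0] <- FALSE
  bad <- which(rowSums(flag) > 0)
  if (length(bad) == nrow(vals)) abort("all epochs rejected")
  out <- ft_subset_rows(psd, setdiff(seq_len(nrow(vals)), bad))
  attr(out, "rejected_epochs") <- bad - 1L
  out
}

#' 0-based original indices of epochs removed by rejection
#' @param x Output of [reject_artifact_epochs()].
#' @return Integer vector (possibly empty).
#' @export
rejected_epochs <- function(x) attr(x, "rejected_epochs") %||% integer(0)

#' Fit the log / z-score / PCA reduction of a feature table
#'
#' Power-like columns (`psd`, `psd_ratio`) are log-transformed; every
#' column is then z-scored (mean 0, SD 1 over epochs) and the table is
#' projected onto its leading principal axes. Components are oriented so
#' each loading vector's largest-magnitude entry is positive. Constant
#' columns (zero SD) are dropped with a warning. The SDA uses 15
#' components; the classifier protocol uses 20.
#'
#' @param features A [feature_table()].
#' @param n_components Number of principal components to keep.
#' @param log_kinds Feature kinds to log-transform.
#' @return A `feature_transform`: list with the fitted centering/scaling,
#'   rotation, kept columns and explained-variance fractions. Apply with
#'   [transform_features()] or `predict()`.
#' @export
fit_feature_transform <- function(features, n_components = 15,
                                  log_kinds = c("psd", "psd_ratio")) {
  meta <- feature_meta(features)
  vals <- ft_values(features)
  if (any(!is.finite(vals))) abort("features must be finite")
  logged <- meta$kind %in% log_kinds
  if (any(vals[, logged] <= 0)) {
    abort("log-transformed kinds require strictly positive values")
  }
  vals[, logged] <- log(vals[, logged])
  mu <- colMeans(vals)
  sdev <- apply(vals, 2, sd)
  keep <- sdev > 0
  if (!all(keep)) {
    warn(sprintf("dropping %d constant column(s) before z-scoring",
                 sum(!keep)))
  }
  if (n_components > min(nrow(vals), sum(keep))) {
    abort("n_components exceeds min(n_epochs, n_features)")
  }
  z <- sweep(sweep(vals[, keep, drop = FALSE], 2, mu[keep], "-"),
             2, sdev[keep], "/")
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  total_var <- sum(pc$sdev^2)
  structure(
    list(
      log_kinds = log_kinds, logged = logged, keep = keep,
      center = mu[keep], scale = sdev[keep], rotation = rot,
      feature_names = meta$feature,
      explained_variance = pc$sdev[seq_len(n_components)]^2 / total_var,
      n_components = n_components
    ),
    class = "feature_transform"
  )
}

#' Apply a fitted transform to a feature table
#'
#' @param features A [feature_table()] with the same columns the transform
#'   was fitted on.
#' @param transform A `feature_transform` from [fit_feature_transform()].
#' @return Numeric matrix, epochs x `n_components`.
#' @export
transform_features <- function(features, transform) {
  meta <- feature_meta(features)
  if (!identical(meta$feature, transform$feature_names)) {
    abort("feature columns differ from those the transform was fitted on")
  }
  vals <- ft_values(features)
  vals[, transform$logged] <- log(vals[, transform$logged])
  z <- sweep(sweep(vals[, transform$keep, drop = FALSE], 2,
                   transform$center, "-"),
             2, transform$scale, "/")
  unname(z %*% transform$rotation)
}

#' @export
predict.feature_transform <- function(object, newdata, ...) {
  transform_features(newdata, object)
}

#' @export
#' @method print feature_transform
print.feature_transform <- function(x, ...) {
  cat(sprintf("<feature_transform> %d features -> %d components (%.1f%% variance)\n",
              length(x$feature_names), x$n_components,
              100 * sum(x$explained_variance)))
  invisible(x)
}

#' @rdname fit_feature_transform
#' @param x A `feature_transform`.
#' @param ... Unused.
#' @export
glance.feature_transform <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_names),
    n_kept = sum(x$keep),
    n_components = x$n_components,
    explained_variance = sum(x$explained_variance)
  )
}

#' Serialise / restore a fitted transform as JSON
#'
#' Lets the identical reduction be replayed on surrogate or rearranged
#' variants of a recording.
#'
#' @param transform A `feature_transform`.
#' @param path JSON path.
#' @return `write_feature_transform()` returns `path` invisibly;
#'   `read_feature_transform()` the restored transform.
#' @export
write_feature_transform <- function(transform, path) {
  obj <- transform
  obj$rotation <- list(values = as.numeric(obj$rotation),
                       dim = dim(obj$rotation))
  jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_transform
#' @export
read_feature_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$rotation <- matrix(obj$rotation$values, nrow = obj$rotation$dim[1])
  obj$logged <- as.logical(obj$logged)
  obj$keep <- as.logical(obj$keep)
  structure(obj, class = "feature_transform")
}
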