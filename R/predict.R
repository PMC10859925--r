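#' Drop sliding-window synchrony features
#'
#' Synchrony features (coherence, PLV and their indices) are computed over
#' 5-epoch windows, so neighbouring epochs leak information across a
#' random train/test split; predictive models therefore use only the
#' power-family columns (75 + 240 = 315 on the standard montage).
#'
#' @param features A [feature_table()].
#' @return A [feature_table()] of `psd` and `psd_ratio` columns.
#' @export
exclude_sync_features <- function(features) {
  meta <- feature_meta(features)
  if (nrow(meta) == 0) abort("empty feature table")
  ft_filter(features, kinds = c("psd", "psd_ratio"))
}

#' Protocol for the state-prediction check
#'
#' @param iv_threshold Keep features with training-split IV at or above
#'   this (per state; union over states for the multiclass task).
#' @param n_components PCA components fitted on the training split.
#' @param test_fraction Held-out fraction of epochs (stratified).
#' @param cv_folds Stratified cross-validation folds for the grid search.
#' @param families Model families to fit: `"svm"` (max-margin),
#'   `"logistic"` (regularised logistic regression), `"xgboost"`
#'   (gradient-boosted trees).
#' @param grids Named list of hyperparameter data frames per family
#'   (defaults cover kernel/cost, penalty/strength and
#'   depth/learning-rate/subsample axes).
#' @param split `"epoch"`: random stratified epoch-level split (the
#'   protocol default); `"block"`: contiguous tail of each state held out,
#'   immune to temporal autocorrelation.
#' @return A list of class `classifier_protocol`.
#' @export
classifier_protocol <- function(iv_threshold = 0.4, n_components = 20,
                                test_fraction = 0.4, cv_folds = 3,
                                families = c("svm", "logistic", "xgboost"),
                                grids = NULL,
                                split = c("epoch", "block")) {
  split <- match.arg(split)
  if (is.null(grids)) {
    grids <- list(
      svm = expand.grid(kernel = c("linear", "radial"),
                        cost = c(0.1, 1, 10), stringsAsFactors = FALSE),
      logistic = expand.grid(alpha = c(0, 1),
                             lambda = c(0.01, 0.1)),
      xgboost = expand.grid(max_depth = c(2, 4), eta = c(0.1, 0.3),
                            subsample = 0.8, nrounds = 50)
    )
  }
  structure(list(iv_threshold = iv_threshold, n_components = n_components,
                 test_fraction = test_fraction, cv_folds = cv_folds,
                 families = families, grids = grids, split = split),
            class = "classifier_protocol")
}

stratified_split <- function(y, test_fraction) {
  test <- unlist(lapply(split(seq_along(y), y), function(ix) {
    n_test <- max(1L, round(length(ix) * test_fraction))
    sample(ix, n_test)
  }))
  list(train = setdiff(seq_along(y), test), test = sort(test))
}

block_split <- function(y, test_fraction) {
  test <- unlist(lapply(split(seq_along(y), y), function(ix) {
    n_test <- max(1L, round(length(ix) * test_fraction))
    tail(ix, n_test)
  }))
  list(train = setdiff(seq_along(y), test), test = sort(test))
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (ix in split(seq_along(y), y)) {
    folds[ix] <- rep_len(sample(k), length(ix))
  }
  folds
}

# IV filter + z-score + PCA, fitted on the training rows only
fit_preprocessor <- function(x, labels, train, iv_threshold, n_components) {
  xtr <- x[train, , drop = FALSE]
  ytr <- labels[train]
  states <- sort(unique(ytr))
  keep <- rep(FALSE, ncol(x))
  for (s in states) {
    ivs <- vapply(seq_len(ncol(x)), function(j) {
      woe_iv(xtr[, j], ytr == s)$iv
    }, numeric(1))
    keep <- keep | ivs >= iv_threshold
  }
  if (!any(keep)) {
    warn("no feature reaches the IV threshold on the training split; keeping all")
    keep <- rep(TRUE, ncol(x))
  }
  xk <- xtr[, keep, drop = FALSE]
  mu <- colMeans(xk)
  sdev <- apply(xk, 2, sd)
  sdev[sdev == 0] <- 1
  z <- sweep(sweep(xk, 2, mu, "-"), 2, sdev, "/")
  ncomp <- min(n_components, ncol(z), nrow(z) - 1L)
  rot <- prcomp(z, center = FALSE)$rotation[, seq_len(ncomp), drop = FALSE]
  list(keep = keep, mu = mu, sd = sdev, rot = rot)
}

apply_preprocessor <- function(prep, x) {
  z <- sweep(sweep(x[, prep$keep, drop = FALSE], 2, prep$mu, "-"),
             2, prep$sd, "/")
  z %*% prep$rot
}

fit_one_model <- function(family, params, x, y) {
  y <- factor(y)
  switch(family,
    svm = e1071::svm(x, y, kernel = params$kernel, cost = params$cost,
                     probability = TRUE),
    logistic = {
      if (ncol(x) < 2) x <- cbind(x, `.pad` = 0)  # glmnet needs >= 2 cols
      glmnet::glmnet(
        x, y, family = if (nlevels(y) > 2) "multinomial" else "binomial",
        alpha = params$alpha, lambda = params$lambda
      )
    },
    xgboost = {
      d <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      nc <- nlevels(y)
      par <- list(max_depth = params$max_depth, eta = params$eta,
                  subsample = params$subsample, nthread = 1,
                  objective = if (nc > 2) "multi:softprob"
                              else "binary:logistic")
      if (nc > 2) par$num_class <- nc
      xgboost::xgb.train(par, d, nrounds = params$nrounds, verbose = 0)
    }
  )
}

# probability matrix (rows sum ~1) with columns in level order
predict_prob <- function(family, model, x, levels) {
  switch(family,
    svm = {
      pr <- attr(predict(model, x, probability = TRUE), "probabilities")
      pr[, levels, drop = FALSE]
    },
    logistic = {
      if (ncol(x) < model$dim[1]) {
        x <- cbind(x, matrix(0, nrow(x), model$dim[1] - ncol(x)))
      }
      pr <- predict(model, x, type = "response")
      if (length(dim(pr)) == 3) {
        pr <- pr[, , 1]
        pr[, levels, drop = FALSE]
      } else {
        cbind(1 - pr[, 1], pr[, 1]) |>
          (\(m) { colnames(m) <- levels; m })()
      }
    },
    xgboost = {
      pr <- predict(model, xgboost::xgb.DMatrix(x))
      if (length(levels) > 2) {
        m <- matrix(pr, ncol = length(levels), byrow = TRUE)
        colnames(m) <- levels
        m
      } else {
        m <- cbind(1 - pr, pr)
        colnames(m) <- levels
        m
      }
    }
  )
}

predict_class <- function(prob) colnames(prob)[max.col(prob, "first")]

macro_f1 <- function(truth, pred, levels) {
  f1 <- vapply(levels, function(l) {
    tp <- sum(truth == l & pred == l)
    fp <- sum(truth != l & pred == l)
    fn <- sum(truth == l & pred != l)
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  mean(f1)
}

balanced_accuracy <- function(truth, pred) {
  mean(vapply(unique(truth), function(l) {
    mean(pred[truth == l] == l)
  }, numeric(1)))
}

cv_score <- function(family, params, x, y, folds, binary) {
  scores <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    if (length(unique(y[tr])) < length(unique(y))) return(NA_real_)
    m <- fit_one_model(family, params, x[tr, , drop = FALSE], y[tr])
    pr <- predict_prob(family, m, x[!tr, , drop = FALSE],
                       levels(factor(y)))
    pred <- predict_class(pr)
    if (binary) balanced_accuracy(y[!tr], pred)
    else mean(pred == y[!tr])
  }, numeric(1))
  mean(scores, na.rm = TRUE)
}

#' Predict SDA states from power features (external separability check)
#'
#' Implements the validation protocol: power-family features only, an IV
#' filter (threshold on the training split), z-scoring and a PCA
#' projection fitted on the training split, a stratified held-out split,
#' and a small grid search with stratified cross-validation per model
#' family. Reports the multiclass task (accuracy, macro F1, confusion
#' matrix) and one binary task per state (balanced accuracy, ROC AUC, ROC
#' points) on the held-out epochs. Chance-level results on surrogate data
#' (balanced accuracy and AUC near 0.5) are the expected null behaviour.
#'
#' @param features A [feature_table()]; synchrony columns are dropped via
#'   [exclude_sync_features()] if present.
#' @param p A [segment_partition()] providing the target labels.
#' @param protocol A [classifier_protocol()].
#' @param seed Integer seed for splitting, folds and model fitting.
#' @param .preprocess_on Internal: fit the IV filter and projection on
#'   `"train"` (the protocol) or `"all"` (leaks the test split; only for
#'   demonstrating the leakage effect).
#' @return A `state_classifiers` object: `multiclass` tibble (per family),
#'   `binary` tibble (per state x family), `confusion` (best multiclass
#'   family), `roc` points, `protocol`.
#' @export
fit_state_classifiers <- function(features, p,
                                  protocol = classifier_protocol(),
                                  seed = 1L,
                                  .preprocess_on = c("train", "all")) {
  .preprocess_on <- match.arg(.preprocess_on)
  meta <- feature_meta(features)
  if (any(!meta$kind %in% c("psd", "psd_ratio"))) {
    features <- exclude_sync_features(features)
  }
  x <- ft_values(features)
  labels <- state_labels(p)
  if (n_states(p) < 2) abort("need at least two states")
  if (any(tabulate(labels) < protocol$cv_folds)) {
    abort("every state needs at least cv_folds epochs")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  sp <- if (protocol$split == "epoch") {
    stratified_split(labels, protocol$test_fraction)
  } else {
    block_split(labels, protocol$test_fraction)
  }
  prep_rows <- if (.preprocess_on == "train") sp$train else seq_along(labels)
  run_task <- function(y) {
    prep <- fit_preprocessor(x, y, prep_rows, protocol$iv_threshold,
                             protocol$n_components)
    xtr <- apply_preprocessor(prep, x)[sp$train, , drop = FALSE]
    xte <- apply_preprocessor(prep, x)[sp$test, , drop = FALSE]
    ytr <- y[sp$train]; yte <- y[sp$test]
    folds <- stratified_folds(ytr, protocol$cv_folds)
    binary <- length(unique(y)) == 2
    fam_out <- list()
    for (fam in protocol$families) {
      grid <- protocol$grids[[fam]]
      cvs <- vapply(seq_len(nrow(grid)), function(g) {
        cv_score(fam, grid[g, , drop = FALSE], xtr, ytr, folds, binary)
      }, numeric(1))
      best <- which.max(cvs)
      model <- fit_one_model(fam, grid[best, , drop = FALSE], xtr, ytr)
      pr <- predict_prob(fam, model, xte, levels(factor(y)))
      pred <- predict_class(pr)
      fam_out[[fam]] <- list(
        family = fam, params = grid[best, , drop = FALSE],
        cv_score = cvs[best], truth = yte, pred = pred, prob = pr
      )
    }
    fam_out
  }

  lvls <- as.character(sort(unique(labels)))
  mc <- run_task(as.character(labels))
  multiclass <- dplyr::bind_rows(lapply(mc, function(r) {
    tibble::tibble(
      family = r$family, cv_score = r$cv_score,
      accuracy = mean(r$pred == r$truth),
      macro_f1 = macro_f1(r$truth, r$pred, lvls),
      best_params = paste(names(r$params), unlist(r$params),
                          sep = "=", collapse = ", ")
    )
  }))
  best_fam <- multiclass$family[which.max(multiclass$accuracy)]
  confusion <- table(truth = factor(mc[[best_fam]]$truth, lvls),
                     pred = factor(mc[[best_fam]]$pred, lvls))

  binary_rows <- list()
  roc_rows <- list()
  for (s in seq_len(n_states(p))) {
    yb <- ifelse(labels == s, "event", "rest")
    res <- run_task(yb)
    for (r in res) {
      score <- r$prob[, "event"]
      auc <- as.numeric(pROC::auc(pROC::roc(
        response = r$truth, predictor = score,
        levels = c("rest", "event"), direction = "<", quiet = TRUE
      )))
      binary_rows[[length(binary_rows) + 1L]] <- tibble::tibble(
        state = s, family = r$family, cv_score = r$cv_score,
        balanced_accuracy = balanced_accuracy(r$truth, r$pred),
        roc_auc = auc
      )
      rc <- pROC::roc(response = r$truth, predictor = score,
                      levels = c("rest", "event"), direction = "<",
                      quiet = TRUE)
      roc_rows[[length(roc_rows) + 1L]] <- tibble::tibble(
        state = s, family = r$family,
        fpr = rev(1 - rc$specificities), tpr = rev(rc$sensitivities)
      )
    }
  }
  structure(
    list(multiclass = multiclass, binary = dplyr::bind_rows(binary_rows),
         confusion = confusion, roc = dplyr::bind_rows(roc_rows),
         protocol = protocol, split = sp, seed = seed),
    class = "state_classifiers"
  )
}

#' @export
#' @method print state_classifiers
print.state_classifiers <- function(x, ...) {
  cat("<state_classifiers>\nmulticlass:\n")
  print(x$multiclass)
  cat("binary (per state):\n")
  print(x$binary)
  invisible(x)
}

#' @rdname fit_state_classifiers
#' @param x A `state_classifiers` object.
#' @param ... Unused.
#' @export
tidy.state_classifiers <- function(x, ...) x$binary

#' @rdname fit_state_classifiers
#' @export
glance.state_classifiers <- function(x, ...) x$multiclass
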