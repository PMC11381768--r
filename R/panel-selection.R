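#' Repeated stratified k-fold cross-validation of the linear SVM
#'
#' Each iteration draws a fresh stratified fold assignment (stratified by
#' class, since case/control cohorts are typically imbalanced), trains one
#' SVM per fold on the remaining folds, and scores the held-out fold.
#' Held-out predictions are pooled within an iteration, so every sample is
#' predicted exactly once per iteration; accuracy, sensitivity and
#' specificity are summarized across iterations with a normal-approximation
#' CI of the mean.  Per-feature importance is the mean squared weight over
#' all `n_iter * folds` fold models.
#'
#' @param x numeric sample-by-feature matrix (already per-sample
#'   L2-normalized where the workflow requires it).
#' @param y labels in `{+1, -1}`; each class must have at least `folds`
#'   members.
#' @param folds number of folds (default 4).
#' @param n_iter number of random re-foldings; the importance phase of the
#'   full protocol uses 2000.
#' @param c SVM soft-margin cost (4 in the discovery phase).
#' @param seed integer seed; identical `(x, y, parameters, seed)` give an
#'   identical result.
#' @param keep_importance set `FALSE` to skip weight accumulation (used
#'   internally by the top-N curve, which only needs accuracies).
#' @return An object of class `cv_result`: `metrics` (one row per
#'   iteration: accuracy, sensitivity, specificity, train_accuracy),
#'   `summary` (mean and 95% CI per metric), `importance` (named
#'   non-negative vector), `n_iterations`, `folds`, `c`.
#' @export
repeated_cv <- function(x, y, folds = 4, n_iter = 2000, c = 4, seed = 1,
                        keep_importance = TRUE) {
  if (!is.matrix(x)) x <- as.matrix(x)
  repeated_cv_core(x, y, tcrossprod(x), folds, n_iter, c, seed,
                   keep_importance)
}

repeated_cv_core <- function(x, y, gram, folds, n_iter, c, seed,
                             keep_importance = TRUE) {
  y <- check_labels(y)
  n <- length(y)
  counts <- table(y)
  if (any(counts < folds))
    stop("each class needs at least ", folds, " samples for ", folds,
         "-fold CV")
  set.seed(as.integer(seed))
  m <- ncol(x)
  imp <- numeric(m)
  acc <- sens <- spec <- tracc <- numeric(n_iter)
  idx_pos <- which(y == 1L)
  idx_neg <- which(y == -1L)
  for (it in seq_len(n_iter)) {
    fold <- integer(n)
    fold[idx_pos] <- sample(rep_len(seq_len(folds), length(idx_pos)))
    fold[idx_neg] <- sample(rep_len(seq_len(folds), length(idx_neg)))
    pred <- integer(n)
    tr_acc_k <- numeric(folds)
    for (k in seq_len(folds)) {
      tr <- which(fold != k)
      te <- which(fold == k)
      sol <- smo_solve(gram[tr, tr, drop = FALSE], y[tr], c, 1e-8, 1000000L)
      av <- sol$alpha * y[tr]
      sc_te <- drop(gram[te, tr, drop = FALSE] %*% av) + sol$b
      pred[te] <- ifelse(sc_te >= 0, 1L, -1L)
      sc_tr <- drop(gram[tr, tr, drop = FALSE] %*% av) + sol$b
      tr_acc_k[k] <- mean(ifelse(sc_tr >= 0, 1L, -1L) == y[tr])
      if (keep_importance) {
        w <- drop(crossprod(x[tr, , drop = FALSE], av))
        imp <- imp + w^2
      }
    }
    cm <- confusion_metrics(y, pred)
    acc[it] <- cm$accuracy
    sens[it] <- cm$sensitivity
    spec[it] <- cm$specificity
    tracc[it] <- mean(tr_acc_k)
  }
  summ <- do.call(rbind, lapply(
    list(accuracy = acc, sensitivity = sens, specificity = spec,
         train_accuracy = tracc),
    function(v) {
      ci <- if (n_iter >= 2) mean_ci(v) else c(mean(v), NA_real_, NA_real_)
      data.frame(mean = ci[1], lower = ci[2], upper = ci[3])
    }))
  summ <- data.frame(metric = rownames(summ), summ, row.names = NULL,
                     stringsAsFactors = FALSE)
  structure(list(
    n_iterations = n_iter, folds = folds, c = c,
    metrics = data.frame(iteration = seq_len(n_iter), accuracy = acc,
                         sensitivity = sens, specificity = spec,
                         train_accuracy = tracc),
    summary = summ,
    importance = if (keep_importance)
      stats::setNames(imp / (n_iter * folds), colnames(x)) else NULL),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d iterations of %d-fold CV (c = %g)\n",
              x$n_iterations, x$folds, x$c))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-15s %.4f (95%% CI %.4f-%.4f)\n", s$metric[i], s$mean[i],
                s$lower[i], s$upper[i]))
  invisible(x)
}

#' Rank features by importance
#'
#' Stable descending sort of the accumulated squared-weight importance; ties
#' are broken by ascending feature index.
#'
#' @param cv a `cv_result` holding importance, or a bare named importance
#'   vector.
#' @return Character vector of feature ids, a permutation of all features.
#' @export
rank_features <- function(cv) {
  imp <- if (inherits(cv, "cv_result")) cv$importance else cv
  if (is.null(imp)) stop("cv does not contain importance")
  ids <- names(imp)
  if (is.null(ids)) ids <- as.character(seq_along(imp))
  ids[order(-imp, seq_along(imp))]
}

#' Progressive top-N accuracy curve
#'
#' For each panel size `N = 1..max_n`, runs [repeated_cv()] on the `N`
#' highest-ranked features and records the mean held-out accuracy, the basis
#' for choosing a minimal panel.  The full protocol uses `max_n = 100` and
#' `n_iter = 500` (100 x 500 x 4 model fits).
#'
#' @inheritParams repeated_cv
#' @param ranking feature ids in importance order, from [rank_features()].
#' @param max_n largest panel size to evaluate (must not exceed the number
#'   of features).
#' @return A data.frame of class `topn_curve`: `n`, `mean_accuracy`,
#'   `lower`, `upper`, `n_iter`.
#' @export
topn_accuracy_curve <- function(x, y, ranking, max_n = 100, folds = 4,
                                n_iter = 500, c = 4, seed = 1) {
  if (!is.matrix(x)) x <- as.matrix(x)
  idx <- match(ranking, colnames(x))
  if (anyNA(idx)) stop("ranking contains unknown feature ids")
  if (max_n > length(idx)) stop("max_n exceeds the number of ranked features")
  n <- nrow(x)
  gram <- matrix(0, n, n)
  out <- vector("list", max_n)
  for (N in seq_len(max_n)) {
    v <- x[, idx[N]]
    gram <- gram + tcrossprod(v)  # incremental Gram over the ranked prefix
    cv <- repeated_cv_core(x[, idx[seq_len(N)], drop = FALSE], y, gram,
                           folds, n_iter, c, seed, keep_importance = FALSE)
    s <- cv$summary[cv$summary$metric == "accuracy", ]
    out[[N]] <- data.frame(n = N, mean_accuracy = s$mean, lower = s$lower,
                           upper = s$upper, n_iter = n_iter)
  }
  curve <- do.call(rbind, out)
  class(curve) <- c("topn_curve", "data.frame")
  curve
}

#' Select a minimal panel from a top-N curve
#'
#' Returns the smallest prefix of the ranking whose mean held-out accuracy
#' is within `tolerance` of the curve's maximum -- improved classification
#' with a relatively small number of features.  An optional availability
#' mask models the downstream chemical-feasibility filter (standard and
#' MS/MS availability): unavailable features are skipped during the ranking
#' traversal, and the curve supplied must have been computed on the filtered
#' ranking.
#'
#' @param curve a `topn_curve`.
#' @param ranking feature ids in importance order (already filtered for
#'   availability if `availability_mask` was used to build the curve).
#' @param tolerance accuracy fraction the panel may concede to the curve
#'   maximum (`0` selects the first maximum).
#' @param availability_mask optional named logical vector; features mapped
#'   to `FALSE` are skipped.
#' @return Character vector of panel feature ids, with attributes `n_star`
#'   and `accuracy`.
#' @export
select_panel <- function(curve, ranking, tolerance = 0.01,
                         availability_mask = NULL) {
  stopifnot(inherits(curve, "topn_curve"))
  if (!is.null(availability_mask)) {
    keep <- availability_mask[ranking]
    keep[is.na(keep)] <- FALSE
    ranking <- ranking[keep]
    if (length(ranking) == 0) stop("no features are available")
  }
  if (nrow(curve) > length(ranking))
    stop("curve is longer than the (available) ranking")
  if (tolerance < 0) stop("tolerance must be >= 0")
  target <- max(curve$mean_accuracy) - tolerance
  n_star <- min(curve$n[curve$mean_accuracy >= target])
  panel <- ranking[seq_len(n_star)]
  attr(panel, "n_star") <- n_star
  attr(panel, "accuracy") <- curve$mean_accuracy[curve$n == n_star]
  panel
}
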