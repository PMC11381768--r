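#' Per-sample L2 normalization
#'
#' Scales a feature vector to unit Euclidean norm,
#' `f_i <- f_i / sqrt(sum_m f_m^2)`.  Applied per sample (row) it uses only
#' that sample's own values, so it can be applied before any
#' cross-validation split without leaking information across samples.
#'
#' @param v numeric vector with at least one non-zero entry.
#' @return `v / sqrt(sum(v^2))`, a unit vector.
#' @export
l2_normalize <- function(v) {
  if (!is.numeric(v) || length(v) < 1) stop("v must be a numeric vector")
  if (any(!is.finite(v))) stop("v must be finite")
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("cannot L2-normalize an all-zero vector")
  v / nrm
}

#' @rdname l2_normalize
#' @param x numeric matrix; each row is normalized independently.
#' @export
l2_normalize_rows <- function(x) {
  if (!is.matrix(x)) stop("x must be a matrix")
  if (any(!is.finite(x))) stop("x must be finite")
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) stop("cannot L2-normalize an all-zero row")
  x / nrm
}

check_labels <- function(y) {
  if (!all(y %in% c(-1L, 1L))) stop("labels must be +1 (case) or -1 (control)")
  if (length(unique(y)) < 2) stop("both classes must be present")
  as.integer(y)
}

#' Train a soft-margin linear SVM
#'
#' Minimizes the primal objective
#' `||w||^2 / 2 + c * sum_i max(0, 1 - y_i (w'x_i + b))`
#' with an unregularized bias, i.e. the standard soft-margin extension of
#' the maximum-margin hyperplane, by sequential minimal optimization on the
#' dual (maximal-violating-pair working sets).  The inferred coefficient
#' vector `w` doubles as the per-feature importance source via
#' [squared_weights()].
#'
#' The optimizer is deterministic; `seed` is accepted for interface
#' uniformity (randomness enters the workflow only through data shuffling).
#'
#' @param x numeric matrix of training samples (rows already L2-normalized
#'   by the caller where the workflow requires it).
#' @param y labels in `{+1, -1}` (case / control).
#' @param c positive soft-margin cost; the discovery phase of the workflow
#'   uses `c = 4` and the targeted validation phase `c = 5`.
#' @param seed unused by the optimizer (kept for contract determinism).
#' @param gram optional precomputed `tcrossprod(x)`; repeated fits on row
#'   subsets of one matrix can share it.
#' @param eps KKT-violation stopping tolerance of the dual solver.
#' @param max_iter iteration cap of the dual solver.
#' @return An object of class `linear_svm` with elements `w`, `b`, `c`,
#'   `objective_value` (primal), `dual_objective`, `alpha`, `feature_ids`.
#' @export
train_linear_svm <- function(x, y, c = 4, seed = 1L, gram = NULL,
                             eps = 1e-8, max_iter = 1000000L) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (any(!is.finite(x))) stop("x must be finite")
  y <- check_labels(y)
  if (nrow(x) != length(y)) stop("nrow(x) must match length(y)")
  if (!is.finite(c) || c <= 0) stop("c must be a positive real")
  if (is.null(gram)) gram <- tcrossprod(x)
  sol <- smo_solve(gram, y, c, eps, as.integer(max_iter))
  av <- sol$alpha * y
  w <- drop(crossprod(x, av))
  b <- sol$b
  margins <- 1 - y * (drop(x %*% w) + b)
  structure(list(w = w, b = b, c = c,
                 objective_value = 0.5 * sum(w^2) + c * sum(pmax(0, margins)),
                 dual_objective = sol$dual_objective, alpha = sol$alpha,
                 iterations = sol$iterations, kkt_gap = sol$kkt_gap,
                 feature_ids = colnames(x)),
            class = "linear_svm")
}

#' Decision values and class predictions
#'
#' `score_i = w'x_i + b`; the predicted class is `sign(score)` with ties
#' (score exactly 0) broken toward +1 (case).
#'
#' @param model a `linear_svm`.
#' @param x numeric matrix with the model's column count.
#' @return `decision_values()`: numeric scores; `predict_svm()`: labels in
#'   `{+1, -1}`.
#' @export
decision_values <- function(model, x) {
  stopifnot(inherits(model, "linear_svm"))
  if (!is.matrix(x)) x <- matrix(x, ncol = length(model$w))
  if (ncol(x) != length(model$w))
    stop("x has ", ncol(x), " columns but the model expects ",
         length(model$w))
  drop(x %*% model$w) + model$b
}

#' @rdname decision_values
#' @export
predict_svm <- function(model, x) {
  ifelse(decision_values(model, x) >= 0, 1L, -1L)
}

#' Squared-weight feature importance
#'
#' The per-feature importance `w_m^2` assigned by a trained linear model:
#' each feature's contribution to the classification, insensitive to the
#' sign of its association.
#'
#' @param model a `linear_svm`.
#' @return Non-negative numeric vector, one entry per feature.
#' @export
squared_weights <- function(model) {
  stopifnot(inherits(model, "linear_svm"))
  stats::setNames(model$w^2, model$feature_ids)
}

#' Serialize / restore a linear SVM as JSON
#'
#' @param model a `linear_svm`.
#' @param path JSON file path.
#' @return `svm_from_json()` returns the restored `linear_svm`.
#' @export
svm_to_json <- function(model, path) {
  stopifnot(inherits(model, "linear_svm"))
  rec <- list(feature_ids = model$feature_ids, w = model$w, b = model$b,
              c = model$c, normalization = "l2_per_sample")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' @rdname svm_to_json
#' @export
svm_from_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(w = as.numeric(rec$w), b = rec$b, c = rec$c,
                 objective_value = NA_real_, dual_objective = NA_real_,
                 alpha = NULL, feature_ids = rec$feature_ids),
            class = "linear_svm")
}
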