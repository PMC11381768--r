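#' Confusion-matrix summary
#'
#' The positive class is the case (+1) group: sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP).
#'
#' @param y_true,y_pred labels in `{+1, -1}`, equal length.
#' @return A list: `tp`, `fp`, `tn`, `fn`, `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("lengths differ")
  if (!all(c(y_true, y_pred) %in% c(-1, 1)))
    stop("labels must be +1 or -1")
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == -1 & y_pred == 1)
  tn <- sum(y_true == -1 & y_pred == -1)
  fn <- sum(y_true == 1 & y_pred == -1)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / length(y_true),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NaN)
}

#' ROC curve and AUC
#'
#' Sweeps all score thresholds from +Inf downwards, yielding an ordered
#' (FPR, TPR) polygon from (0, 0) to (1, 1); the AUC is the trapezoidal area
#' under it, which equals the Mann-Whitney statistic `U / (n+ * n-)` with
#' tied score pairs counted 1/2.
#'
#' @param scores numeric decision values (higher = more case-like).
#' @param labels labels in `{+1, -1}`; both classes must be present.
#' @return A list of class `roc_curve`: `points` (data.frame `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (!all(labels %in% c(-1, 1))) stop("labels must be +1 or -1")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == -1)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  if (anyNA(scores)) stop("scores must not contain NA")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- labels[ord] == 1
  # group tied scores so the curve moves diagonally through ties
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  thr <- c(Inf, s[last])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' Precision-recall curve and average precision
#'
#' Precision and recall at every score threshold (ties grouped); average
#' precision is the step-wise integral `sum (R_k - R_{k-1}) * P_k`.
#'
#' @inheritParams roc_auc
#' @return A list of class `pr_curve`: `points` (data.frame `threshold`,
#'   `recall`, `precision`) and `average_precision`.
#' @export
pr_curve <- function(scores, labels) {
  if (!all(labels %in% c(-1, 1))) stop("labels must be +1 or -1")
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("no positive samples")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- labels[ord] == 1
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(pos)
  n_called <- seq_along(s)
  last <- !duplicated(grp, fromLast = TRUE)
  recall <- tp[last] / n_pos
  precision <- tp[last] / n_called[last]
  ap <- sum(diff(c(0, recall)) * precision)
  structure(list(points = data.frame(threshold = s[last], recall = recall,
                                     precision = precision),
                 average_precision = ap),
            class = "pr_curve")
}

#' Normal-approximation confidence interval of a mean
#'
#' `mean +- z * sd / sqrt(n)` -- the CI-of-the-mean convention used to
#' summarize metrics across cross-validation iterations (which is why
#' reported CIs tighten as the iteration count grows).
#'
#' @param values numeric vector, `n >= 2`.
#' @param level confidence level (default 0.95).
#' @return `c(mean, lower, upper)`.
#' @export
mean_ci <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2) stop("mean_ci needs n >= 2")
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- mean(values)
  hw <- z * stats::sd(values) / sqrt(n)
  c(mean = m, lower = m - hw, upper = m + hw)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment controlling the false discovery rate;
#' rejecting adjusted values at `q` reproduces the largest-k rule
#' `p_(k) <= k q / m`.
#'
#' @param pvalues numeric vector in `[0, 1]` (NA allowed).
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Two-sample group difference test
#'
#' Welch's two-sample t-test (unequal variances, Welch-Satterthwaite
#' degrees of freedom) by default; set `var_equal = TRUE` for Student's t.
#'
#' @param values numeric vector.
#' @param groups two-level grouping vector aligned with `values`.
#' @param var_equal assume equal variances (default `FALSE`).
#' @return A list: `statistic`, `p_value`, `df`, `estimate` (difference in
#'   means, first level minus second).
#' @export
group_difference_test <- function(values, groups, var_equal = FALSE) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  n <- table(groups[!is.na(values)])
  if (any(n < 2)) stop("both groups need n >= 2")
  ht <- stats::t.test(values ~ groups, var.equal = var_equal)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter),
       estimate = unname(ht$estimate[1] - ht$estimate[2]))
}

#' Metabolite-ratio response-marker analysis
#'
#' Per stratum (e.g. tumor subtype), forms the per-subject concentration
#' ratio `numerator / denominator`, tests the outcome groups on the
#' log-ratio (Welch), and computes the ROC AUC of the ratio against the
#' outcome.  Ratios are scale-free; the log transform symmetrizes them for
#' the test, and since the log is monotone the AUC is identical on either
#' scale.  Subjects with a non-positive denominator are excluded with a
#' warning; strata with a single outcome class report `NA` for AUC and p.
#'
#' @param conc data.frame with `sample_id` and one column per metabolite
#'   (e.g. the `concentrations` element of [generate_nac_cohort()]).
#' @param numerator,denominator metabolite column names (e.g. `"inosine"`,
#'   `"uridine"`).
#' @param outcome_labels two-level outcome aligned with `conc` rows; the
#'   FIRST level sorted alphabetically is taken as negative unless a factor
#'   is supplied -- pass a factor with levels `c(negative, positive)` to fix
#'   the AUC direction.
#' @param strata stratum label per row (e.g. subtype); `NULL` for a single
#'   stratum.
#' @return data.frame: `stratum`, `n`, `p_value`, `auc`, `mean_log_ratio_pos`,
#'   `mean_log_ratio_neg`.
#' @export
ratio_marker_analysis <- function(conc, numerator, denominator,
                                  outcome_labels, strata = NULL) {
  if (!all(c(numerator, denominator) %in% names(conc)))
    stop("numerator and denominator must be columns of conc")
  num <- conc[[numerator]]
  den <- conc[[denominator]]
  if (is.null(strata)) strata <- rep("all", nrow(conc))
  outcome_labels <- as.factor(outcome_labels)
  if (nlevels(outcome_labels) != 2) stop("outcome must have two levels")
  pos_level <- levels(outcome_labels)[2]

  bad <- is.na(den) | den <= 0 | is.na(num)
  if (any(bad)) {
    warning(sum(bad), " subject(s) excluded (non-positive or missing ",
            "denominator/numerator)")
    num <- num[!bad]; den <- den[!bad]
    strata <- strata[!bad]; outcome_labels <- outcome_labels[!bad]
  }
  ratio <- num / den
  out <- lapply(unique(strata), function(s) {
    sel <- strata == s
    y <- outcome_labels[sel]
    r <- ratio[sel]
    res <- data.frame(stratum = s, n = sum(sel), p_value = NA_real_,
                      auc = NA_real_, mean_log_ratio_pos = NA_real_,
                      mean_log_ratio_neg = NA_real_,
                      stringsAsFactors = FALSE)
    if (length(unique(y)) == 2 && all(table(y) >= 2)) {
      tt <- group_difference_test(log(r), y)
      res$p_value <- tt$p_value
      res$auc <- roc_auc(r, ifelse(y == pos_level, 1, -1))$auc
    }
    res$mean_log_ratio_pos <- mean(log(r[y == pos_level]))
    res$mean_log_ratio_neg <- mean(log(r[y != pos_level]))
    res
  })
  do.call(rbind, out)
}

#' Export ROC / PR point sets as TSV
#' @param curve a `roc_curve` or `pr_curve`.
#' @param path TSV path.
#' @export
write_curve_points <- function(curve, path) {
  utils::write.table(curve$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(curve)
}
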