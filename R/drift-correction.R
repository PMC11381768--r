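#' Impute below-detection intensities
#'
#' Replaces every missing entry of a feature with 1/10 of the minimum
#' observed peak intensity of that feature across all samples, the standard
#' below-detection substitution applied when exporting aligned feature
#' tables.  Features with no observed value at all cannot be imputed and are
#' dropped with a warning.
#'
#' @param table a [feature_table()].
#' @return A `feature_table` with no missing entries (possibly fewer
#'   features); present entries are unchanged.
#' @export
impute_missing <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$intensities
  all_missing <- colSums(!is.na(x)) == 0L
  if (any(all_missing)) {
    warning("dropping ", sum(all_missing),
            " feature(s) with no observed values: ",
            paste(colnames(x)[all_missing], collapse = ", "))
    x <- x[, !all_missing, drop = FALSE]
  }
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- min(x[!nas, j]) / 10
  }
  out <- feature_table(x, table$metadata)
  attr(out, "truth") <- attr(table, "truth")
  out
}

#' Relative standard deviation
#'
#' `sd(values) / mean(values)`, the per-feature QC stability metric.
#'
#' @param values numeric vector of at least two values.
#' @return The RSD as a fraction.
#' @export
feature_rsd <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("feature_rsd needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("feature_rsd undefined for zero mean")
  stats::sd(values) / m
}

#' Fit a QC intensity trend over injection order
#'
#' Smooths the pooled-QC intensities of one feature as a function of
#' injection order.  Two interchangeable fitters are provided:
#' `"loess_like"`, a local-linear smoother (plain linear interpolation when
#' fewer than 6 QC points are available, so it reproduces small hand-checked
#' cases exactly), and `"ensemble_regression"`, an averaged ensemble of
#' interpolants fitted to bootstrap resamples of the QC points (seeded,
#' hence deterministic).  Both reproduce a constant or exactly linear QC
#' profile without error.  Predictions outside the QC order range are
#' clamped to the nearest QC prediction.
#'
#' @param qc_intensities positive QC intensities of one feature.
#' @param qc_orders injection orders of the QC samples.
#' @param method `"loess_like"` or `"ensemble_regression"`
#'   (`ensemble_regression` needs at least 3 QC points, `loess_like` at
#'   least 2; with fewer, the error instructs falling back to a global
#'   median factor).
#' @param seed integer seed for the bootstrap ensemble.
#' @param n_boot ensemble size.
#' @return An object of class `trend_model` with the fitted grid, the
#'   `reference_level` (median QC intensity) and the fitting method.
#' @export
fit_qc_trend <- function(qc_intensities, qc_orders,
                         method = c("loess_like", "ensemble_regression"),
                         seed = 1, n_boot = 50) {
  method <- match.arg(method)
  if (length(qc_intensities) != length(qc_orders))
    stop("qc_intensities and qc_orders must have equal length")
  keep <- !is.na(qc_intensities)
  qc_intensities <- qc_intensities[keep]
  qc_orders <- qc_orders[keep]
  min_pts <- if (method == "ensemble_regression") 3L else 2L
  if (length(qc_intensities) < min_pts)
    stop("fewer than ", min_pts, " QC points: fall back to a global-median ",
         "correction factor for this feature")
  if (any(qc_intensities <= 0)) stop("QC intensities must be positive")
  o <- order(qc_orders)
  qc_orders <- qc_orders[o]
  qc_intensities <- qc_intensities[o]
  # duplicate orders (e.g. re-injections) are averaged before smoothing
  if (anyDuplicated(qc_orders) > 0) {
    agg <- tapply(qc_intensities, qc_orders, mean)
    qc_orders <- as.numeric(names(agg))
    qc_intensities <- as.numeric(agg)
  }
  grid <- seq(min(qc_orders), max(qc_orders))
  pred <- switch(method,
    loess_like = {
      if (length(qc_orders) >= 6) {
        fit <- stats::loess(qc_intensities ~ qc_orders, span = 0.75,
                            degree = 1, surface = "direct",
                            family = "gaussian")
        as.numeric(stats::predict(fit, data.frame(qc_orders = grid)))
      } else {
        stats::approx(qc_orders, qc_intensities, xout = grid, rule = 2)$y
      }
    },
    ensemble_regression = {
      set.seed(as.integer(seed))
      n <- length(qc_orders)
      ends <- c(1L, n)  # keep the range ends so members never extrapolate
      acc <- numeric(length(grid))
      for (b in seq_len(n_boot)) {
        idx <- c(ends, sample.int(n, n, replace = TRUE))
        agg <- tapply(qc_intensities[idx], qc_orders[idx], mean)
        acc <- acc + stats::approx(as.numeric(names(agg)), as.numeric(agg),
                                   xout = grid, rule = 2)$y
      }
      acc / n_boot
    })
  structure(list(method = method, grid = grid, prediction = pred,
                 reference_level = stats::median(qc_intensities),
                 qc_orders = qc_orders, qc_intensities = qc_intensities),
            class = "trend_model")
}

#' Predict a fitted QC trend at given injection orders
#'
#' Orders outside the fitted QC range are clamped to the range edges, so the
#' trend never extrapolates.
#'
#' @param trend a `trend_model` from [fit_qc_trend()].
#' @param orders injection orders.
#' @return Predicted QC-scale intensities.
#' @export
predict_trend <- function(trend, orders) {
  stopifnot(inherits(trend, "trend_model"))
  orders <- pmin(pmax(orders, min(trend$grid)), max(trend$grid))
  stats::approx(trend$grid, trend$prediction, xout = orders)$y
}

#' Fit per-feature QC trends for every batch of a feature table
#'
#' @param table an imputed [feature_table()].
#' @param method trend fitter, see [fit_qc_trend()].
#' @param seed integer seed (ensemble method only).
#' @return A nested list `trends[[batch]][[feature_id]]`; entries are
#'   `trend_model` objects or `NULL` where fitting failed (too few QC
#'   points).  Attribute `reference_levels` holds the per-feature median QC
#'   intensity pooled over batches.
#' @export
fit_qc_trends <- function(table, method = c("loess_like",
                                            "ensemble_regression"),
                          seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(table, "feature_table"))
  md <- table$metadata
  qc <- md$role == "qc"
  if (sum(qc) < 2) stop("drift correction needs at least 2 QC injections")
  batches <- unique(md$batch)
  trends <- lapply(batches, function(b) {
    rows <- qc & md$batch == b
    lapply(stats::setNames(seq_len(ncol(table$intensities)),
                           colnames(table$intensities)), function(j) {
      tryCatch(fit_qc_trend(table$intensities[rows, j],
                            md$injection_order[rows], method = method,
                            seed = seed + j),
               error = function(e) NULL)
    })
  })
  names(trends) <- as.character(batches)
  attr(trends, "reference_levels") <-
    apply(table$intensities[qc, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  trends
}

#' Remove injection-order signal drift using pooled-QC trends
#'
#' Divides each intensity by the fitted QC trend at its injection order and
#' rescales to the feature's pooled reference level:
#' `corrected(i, j) = raw(i, j) * reference_j / trend_j(order_i)`.
#' Correction is per batch; dividing by the batch's own QC trend and
#' rescaling to the pooled reference level also harmonizes batch offsets.
#' A feature is left uncorrected (and flagged) when its trend fit failed,
#' when a trend prediction is non-positive, or when the correction would
#' increase the feature's QC RSD -- so corrected features always satisfy
#' `rsd_after <= rsd_before`.
#'
#' @param table an imputed [feature_table()].
#' @param trends output of [fit_qc_trends()] for the same table.
#' @return A list with `table` (corrected `feature_table`) and `qc_report`
#'   (data.frame `feature_id`, `rsd_before`, `rsd_after`, `corrected`,
#'   `reason`).
#' @export
apply_drift_correction <- function(table, trends) {
  stopifnot(inherits(table, "feature_table"))
  md <- table$metadata
  qc <- md$role == "qc"
  raw <- table$intensities
  if (anyNA(raw)) stop("impute missing values before drift correction")
  ref <- attr(trends, "reference_levels")
  corrected <- raw
  reason <- rep("", ncol(raw))
  ok <- rep(TRUE, ncol(raw))
  for (b in names(trends)) {
    rows <- which(md$batch == b)
    for (j in seq_len(ncol(raw))) {
      if (!ok[j]) next
      tm <- trends[[b]][[colnames(raw)[j]]]
      if (is.null(tm)) {
        ok[j] <- FALSE
        reason[j] <- "trend_fit_failed"
        next
      }
      pred <- predict_trend(tm, md$injection_order[rows])
      if (any(pred <= 0)) {
        ok[j] <- FALSE
        reason[j] <- "nonpositive_trend"
        next
      }
      corrected[rows, j] <- raw[rows, j] * ref[j] / pred
    }
  }
  rsd_before <- apply(raw[qc, , drop = FALSE], 2, feature_rsd)
  rsd_after <- rsd_before
  for (j in seq_len(ncol(raw))) {
    if (!ok[j]) {
      corrected[, j] <- raw[, j]
      next
    }
    rsd_j <- feature_rsd(corrected[qc, j])
    if (rsd_j > rsd_before[j] + 1e-9) {
      ok[j] <- FALSE
      reason[j] <- "rsd_increase"
      corrected[, j] <- raw[, j]
    } else {
      rsd_after[j] <- rsd_j
    }
  }
  out <- feature_table(corrected, md)
  attr(out, "truth") <- attr(table, "truth")
  list(table = out,
       qc_report = data.frame(feature_id = colnames(raw),
                              rsd_before = rsd_before, rsd_after = rsd_after,
                              corrected = ifelse(ok, "yes", "no"),
                              reason = reason, row.names = NULL,
                              stringsAsFactors = FALSE))
}

#' One-call drift correction
#'
#' Convenience wrapper: fits per-batch QC trends and applies the correction.
#'
#' @inheritParams fit_qc_trends
#' @return As [apply_drift_correction()].
#' @export
correct_drift <- function(table, method = c("loess_like",
                                            "ensemble_regression"),
                          seed = 1) {
  method <- match.arg(method)
  apply_drift_correction(table, fit_qc_trends(table, method, seed))
}

#' Write a per-feature QC drift report as TSV
#' @param qc_report the `qc_report` component of [apply_drift_correction()].
#' @param path TSV path.
#' @export
write_qc_report <- function(qc_report, path) {
  utils::write.table(qc_report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(qc_report)
}
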