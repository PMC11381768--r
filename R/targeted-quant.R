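#' Response ratio of analyte to internal standard
#'
#' The calibrated quantity of stable-isotope-dilution assays: analyte peak
#' area divided by the co-eluting labeled internal-standard peak area, which
#' cancels matrix effects and detector gain.  Records with a non-positive IS
#' area are unquantifiable and return `NA`.
#'
#' @param analyte_area,is_area peak areas (vectorized).
#' @return `analyte_area / is_area`, `NA` where `is_area <= 0`.
#' @export
response_ratio <- function(analyte_area, is_area) {
  out <- analyte_area / is_area
  bad <- !is.na(is_area) & is_area <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) flagged unquantifiable (IS area <= 0)")
    out[bad] <- NA_real_
  }
  out
}

#' Fit a weighted least-squares calibration curve
#'
#' Regresses the response ratio on the nominal concentration with weights
#' `1 / x^weighting_exponent` (the bioanalytical standard is `1/x^2`, which
#' equalizes relative errors across a wide calibration range; exponent 0
#' recovers ordinary least squares).  The fit minimizes
#' `sum_k (1/x_k^e) * (r_k - (slope * x_k + intercept))^2`.
#'
#' Back-calculated concentrations, per-level bias, the acceptance decision
#' (via [validate_curve()]) and LLOQ/LLOD (via [estimate_limits()]) are
#' attached to the returned curve.
#'
#' @param calibrators data.frame with columns `nominal_conc` and either
#'   `ratio` or (`analyte_area`, `is_area`).
#' @param weighting_exponent non-negative weighting exponent (default 2).
#' @param analyte analyte name carried into the curve.
#' @return An object of class `calibration_curve`: `slope`, `intercept`,
#'   `weighting_exponent`, `r_squared` (weighted), `levels` (per-level
#'   back-calculation report), `accepted`, `lloq`, `llod`, `sigma_low`.
#' @export
fit_calibration <- function(calibrators, weighting_exponent = 2,
                            analyte = NA_character_) {
  if (!"ratio" %in% names(calibrators)) {
    if (!all(c("analyte_area", "is_area") %in% names(calibrators)))
      stop("calibrators need a ratio column or analyte_area + is_area")
    calibrators$ratio <- response_ratio(calibrators$analyte_area,
                                        calibrators$is_area)
  }
  calibrators <- calibrators[!is.na(calibrators$ratio), , drop = FALSE]
  x <- calibrators$nominal_conc
  r <- calibrators$ratio
  if (length(unique(x)) < 6)
    stop("calibration needs >= 6 usable calibrator levels with distinct ",
         "concentrations")
  if (weighting_exponent > 0 && any(x <= 0))
    stop("1/x^", weighting_exponent,
         " weighting is undefined at non-positive concentrations")
  if (weighting_exponent < 0) stop("weighting_exponent must be >= 0")
  w <- if (weighting_exponent == 0) rep(1, length(x)) else
    1 / x^weighting_exponent
  fit <- stats::lm(r ~ x, weights = w)
  slope <- unname(stats::coef(fit)["x"])
  intercept <- unname(stats::coef(fit)["(Intercept)"])
  rbar <- sum(w * r) / sum(w)
  r2 <- 1 - sum(w * stats::residuals(fit)^2) / sum(w * (r - rbar)^2)

  curve <- structure(list(analyte = analyte, slope = slope,
                          intercept = intercept,
                          weighting_exponent = weighting_exponent,
                          r_squared = r2),
                     class = "calibration_curve")
  report <- validate_curve(curve, calibrators)
  curve$levels <- report$levels
  curve$accepted <- report$accepted
  limits <- estimate_limits(calibrators, curve)
  curve$lloq <- limits[["lloq"]]
  curve$llod <- limits[["llod"]]
  curve$sigma_low <- attr(limits, "sigma")
  curve
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "calibration_curve [%s]: ratio = %.6g * conc + %.6g (1/x^%g weights)\n",
    x$analyte, x$slope, x$intercept, x$weighting_exponent))
  cat(sprintf("  weighted R^2 = %.6f; %s; LLOQ = %.4g, LLOD = %.4g\n",
              x$r_squared, if (isTRUE(x$accepted)) "accepted" else "rejected",
              x$lloq, x$llod))
  invisible(x)
}

#' Back-calculate a concentration from a response ratio
#'
#' Inverts the calibration line: `conc = (ratio - intercept) / slope`.
#' Negative results are reported as-is with a below-zero flag rather than
#' censored.
#'
#' @param curve a `calibration_curve` with positive slope.
#' @param ratio response ratio(s).
#' @return Concentrations (ng/mL) with attribute `below_zero`.
#' @export
back_calculate <- function(curve, ratio) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(curve$slope) || curve$slope <= 0)
    stop("back-calculation requires a positive slope")
  conc <- (ratio - curve$intercept) / curve$slope
  attr(conc, "below_zero") <- !is.na(conc) & conc < 0
  conc
}

#' Back-calculation acceptance of a calibration curve
#'
#' Each calibrator level is back-calculated through the fitted line; a level
#' passes when its relative bias `(back_calc - nominal) / nominal` is within
#' +-15% (+-20% at the lowest level, the LLOQ tolerance).  The curve is
#' accepted when at least 75% of the levels pass.
#'
#' @param curve a `calibration_curve`.
#' @param calibrators data.frame with `nominal_conc` and `ratio` (or areas).
#' @return A list: `levels` (per-level nominal, ratio, back-calculated
#'   concentration, bias, tolerance, pass), `n_pass`, `n_levels`,
#'   `pass_fraction`, `accepted`, `failing_levels`.
#' @export
validate_curve <- function(curve, calibrators) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!"ratio" %in% names(calibrators))
    calibrators$ratio <- response_ratio(calibrators$analyte_area,
                                        calibrators$is_area)
  ok <- !is.na(calibrators$ratio)
  x <- calibrators$nominal_conc[ok]
  r <- calibrators$ratio[ok]
  bc <- as.numeric(back_calculate(curve, r))
  bias <- (bc - x) / x
  tol <- ifelse(x == min(x), 0.20, 0.15)
  pass <- abs(bias) <= tol
  levels <- data.frame(nominal_conc = x, ratio = r, back_calc = bc,
                       bias = bias, tolerance = tol, pass = pass)
  levels <- levels[order(levels$nominal_conc), ]
  rownames(levels) <- NULL
  list(levels = levels, n_pass = sum(pass), n_levels = length(pass),
       pass_fraction = mean(pass), accepted = mean(pass) >= 0.75,
       failing_levels = levels$nominal_conc[!levels$pass])
}

#' Estimate LLOQ and LLOD
#'
#' LLOQ is the lowest calibrator level whose back-calculated bias is within
#' +-20% and, where replicate QC measurements at (or below) that level are
#' available, whose replicate CV is <= 20%.  LLOD uses the `3.3 * sigma /
#' slope` convention with `sigma` the residual SD of the lowest calibrator
#' levels (or a caller-supplied value).
#'
#' @param calibrators data.frame with `nominal_conc` and `ratio` (or areas).
#' @param curve a fitted `calibration_curve`.
#' @param replicate_qcs optional data.frame with `nominal_conc` and `ratio`
#'   columns of replicated QC measurements for the precision check.
#' @param sigma optional residual SD (ratio units) overriding the estimate.
#' @param n_low number of lowest levels used for the residual SD.
#' @return Named vector `c(lloq = , llod = )` (LLOQ is `NaN`, with a
#'   warning, when no level qualifies); attribute `sigma` holds the residual
#'   SD used.
#' @export
estimate_limits <- function(calibrators, curve, replicate_qcs = NULL,
                            sigma = NULL, n_low = 3) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!"ratio" %in% names(calibrators))
    calibrators$ratio <- response_ratio(calibrators$analyte_area,
                                        calibrators$is_area)
  ord <- order(calibrators$nominal_conc)
  x <- calibrators$nominal_conc[ord]
  r <- calibrators$ratio[ord]
  bc <- as.numeric(back_calculate(curve, r))
  bias <- (bc - x) / x

  lloq <- NaN
  for (lv in unique(x)) {
    sel <- x == lv
    if (any(abs(bias[sel]) > 0.20)) next
    if (!is.null(replicate_qcs)) {
      reps <- replicate_qcs$ratio[replicate_qcs$nominal_conc <= lv]
      if (length(reps) >= 2 && feature_rsd(reps) > 0.20) next
    }
    lloq <- lv
    break
  }
  if (is.nan(lloq))
    warning("no calibrator level meets the LLOQ criteria; curve flagged")

  if (is.null(sigma)) {
    low <- seq_len(min(n_low, length(r)))
    resid <- r[low] - (curve$slope * x[low] + curve$intercept)
    sigma <- stats::sd(resid)
    if (is.na(sigma)) sigma <- 0
  }
  out <- c(lloq = lloq, llod = 3.3 * sigma / curve$slope)
  attr(out, "sigma") <- sigma
  out
}

#' Quantify QC and subject samples against fitted calibration curves
#'
#' Back-calculates absolute concentrations for every non-calibrator record
#' of a targeted run.  Values below the analyte's LLOQ are retained
#' numerically but flagged (censoring them would silently change the
#' concentration distribution the downstream classifier sees); records with
#' a missing or non-positive IS area yield `NA` with a flag.
#'
#' @param run a `targeted_run` data.frame (see [generate_targeted_run()] for
#'   the column dialect).
#' @param curves named list of accepted `calibration_curve` objects, one per
#'   analyte in the run.
#' @param dilution_factor multiplier applied to reported concentrations
#'   (wet-lab reconstitution dilution; default 1, i.e. uncorrected).
#' @return A data.frame of class `concentration_table`: `sample_id`,
#'   `analyte`, `record_type`, `group`, `conc`, `flag`
#'   (`""`/`"below_lloq"`/`"below_zero"`/`"missing_is"`).
#' @export
quantify <- function(run, curves, dilution_factor = 1) {
  analytes <- unique(run$analyte[run$record_type != "calibrator"])
  missing_curves <- setdiff(analytes, names(curves))
  if (length(missing_curves) > 0)
    stop("no calibration curve for: ", paste(missing_curves, collapse = ", "))
  rejected <- analytes[!vapply(curves[analytes],
                               function(cv) isTRUE(cv$accepted), TRUE)]
  if (length(rejected) > 0)
    stop("calibration curve rejected for: ", paste(rejected, collapse = ", "))

  rows <- run[run$record_type != "calibrator", , drop = FALSE]
  out <- lapply(analytes, function(a) {
    rec <- rows[rows$analyte == a, , drop = FALSE]
    ratio <- suppressWarnings(response_ratio(rec$analyte_area, rec$is_area))
    conc <- rep(NA_real_, nrow(rec))
    usable <- !is.na(ratio)
    conc[usable] <- as.numeric(back_calculate(curves[[a]], ratio[usable])) *
      dilution_factor
    flag <- rep("", nrow(rec))
    flag[!usable] <- "missing_is"
    lloq <- curves[[a]]$lloq * dilution_factor
    flag[usable & !is.nan(lloq) & conc < lloq] <- "below_lloq"
    flag[usable & conc < 0] <- "below_zero"
    data.frame(sample_id = rec$sample_id, analyte = a,
               record_type = rec$record_type, group = rec$group, conc = conc,
               flag = flag, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("concentration_table", "data.frame")
  res
}

#' Reshape a long concentration table into a sample-by-analyte matrix
#'
#' @param conc a `concentration_table`.
#' @param record_type which records to keep (default subjects).
#' @return A list: `x` (numeric matrix, samples x analytes), `group`
#'   (character vector aligned with rows).
#' @export
concentration_matrix <- function(conc, record_type = "subject") {
  rows <- conc[conc$record_type %in% record_type, , drop = FALSE]
  ids <- unique(rows$sample_id)
  analytes <- unique(rows$analyte)
  x <- matrix(NA_real_, length(ids), length(analytes),
              dimnames = list(ids, analytes))
  x[cbind(match(rows$sample_id, ids), match(rows$analyte, analytes))] <-
    rows$conc
  group <- rows$group[match(ids, rows$sample_id)]
  list(x = x, group = group)
}
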