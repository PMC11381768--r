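make_line_calibrators <- function(slope = 0.02, intercept = 0.001,
                                  levels = 0.5 * 2^(0:12)) {
  data.frame(nominal_conc = levels, ratio = slope * levels + intercept)
}

test_that("response_ratio divides areas and flags bad internal standards", {
  expect_equal(response_ratio(5000, 10000), 0.5)
  expect_equal(response_ratio(0, 10000), 0)
  k <- 3.7
  expect_equal(response_ratio(k * 123, k * 456), 123 / 456)
  expect_warning(out <- response_ratio(c(10, 10), c(100, 0)),
                 "unquantifiable")
  expect_equal(out, c(0.1, NA))
})

test_that("noise-free calibrators are recovered exactly", {
  cal <- make_line_calibrators(slope = 0.02, intercept = 0.001)
  curve <- fit_calibration(cal, weighting_exponent = 2)
  expect_equal(curve$slope, 0.02, tolerance = 1e-12)
  expect_equal(curve$intercept, 0.001, tolerance = 1e-12)
  expect_equal(curve$r_squared, 1, tolerance = 1e-12)
  expect_true(curve$accepted)
  expect_true(all(curve$levels$pass))
  # round trip through back-calculation
  expect_equal(as.numeric(back_calculate(curve, cal$ratio)),
               cal$nominal_conc, tolerance = 1e-10)
})

test_that("weighted fits match explicit normal equations", {
  set.seed(14)
  for (rep in 1:25) {
    x <- sort(stats::runif(13, 0.5, 500))
    r <- 0.01 * x + 0.002 + stats::rnorm(13, 0, 0.05 * (0.01 * x))
    for (e in c(0, 1, 2)) {
      curve <- fit_calibration(data.frame(nominal_conc = x, ratio = r),
                               weighting_exponent = e)
      ref <- wls_normal_equations(x, r, e)
      expect_equal(curve$slope, unname(ref["slope"]), tolerance = 1e-10)
      expect_equal(curve$intercept, unname(ref["intercept"]),
                   tolerance = 1e-10)
    }
  }
})

test_that("exponent 0 reduces to ordinary least squares", {
  set.seed(15)
  x <- 2^(0:12)
  r <- 0.05 * x + 0.01 + stats::rnorm(13, 0, 0.02)
  curve <- fit_calibration(data.frame(nominal_conc = x, ratio = r),
                           weighting_exponent = 0)
  ols <- stats::lm(r ~ x)
  expect_equal(curve$slope, unname(stats::coef(ols)["x"]), tolerance = 1e-12)
  expect_equal(curve$intercept, unname(stats::coef(ols)["(Intercept)"]),
               tolerance = 1e-12)
})

test_that("1/x^2 weighting beats OLS at the low end under proportional noise", {
  set.seed(16)
  levels <- 0.5 * 2^(0:12)
  wins <- replicate(200, {
    r <- (0.02 * levels + 0.001) * exp(stats::rnorm(13, 0, 0.05))
    cal <- data.frame(nominal_conc = levels, ratio = r)
    low_bias <- function(e) {
      curve <- suppressWarnings(fit_calibration(cal, weighting_exponent = e))
      abs(as.numeric(back_calculate(curve, r[1])) - levels[1]) / levels[1]
    }
    c(weighted = low_bias(2), ols = low_bias(0))
  })
  expect_lt(stats::median(wins["weighted", ]), stats::median(wins["ols", ]))
})

test_that("calibration rejects unusable designs", {
  expect_error(fit_calibration(data.frame(nominal_conc = 1:5,
                                          ratio = 1:5 * 0.1)), ">= 6")
  expect_error(fit_calibration(data.frame(nominal_conc = c(0, 1:9),
                                          ratio = 0:9 * 0.1),
                               weighting_exponent = 2), "undefined")
  curve <- fit_calibration(make_line_calibrators())
  neg <- curve
  neg$slope <- -0.1
  expect_error(back_calculate(neg, 0.5), "positive slope")
})

test_that("back-calculation inverts the line to machine precision", {
  set.seed(17)
  for (rep in 1:20) {
    curve <- structure(list(slope = stats::runif(1, 1e-4, 10),
                            intercept = stats::rnorm(1, 0, 0.1)),
                       class = "calibration_curve")
    ratio <- stats::runif(5, 0, 20)
    conc <- as.numeric(back_calculate(curve, ratio))
    expect_equal(conc, (ratio - curve$intercept) / curve$slope,
                 tolerance = 1e-12)
    expect_equal(curve$slope * conc + curve$intercept, ratio,
                 tolerance = 1e-12)
  }
  curve <- structure(list(slope = 0.02, intercept = 0), class = "calibration_curve")
  expect_equal(as.numeric(back_calculate(curve, 0.5)), 25)
  bc <- back_calculate(curve, c(0.5, -0.1))
  expect_equal(attr(bc, "below_zero"), c(FALSE, TRUE))
})

test_that("acceptance boundary is >= 75% of calibrator levels", {
  cal <- make_line_calibrators()
  curve <- fit_calibration(cal)
  biased3 <- cal
  biased3$ratio[c(5, 8, 11)] <- biased3$ratio[c(5, 8, 11)] * 1.3
  rep3 <- validate_curve(curve, biased3)
  expect_equal(rep3$n_pass, 10)
  expect_true(rep3$accepted)  # 10/13 = 76.9% >= 75%
  biased4 <- cal
  biased4$ratio[c(5, 8, 11, 12)] <- biased4$ratio[c(5, 8, 11, 12)] * 1.3
  rep4 <- validate_curve(curve, biased4)
  expect_equal(rep4$n_pass, 9)
  expect_false(rep4$accepted)  # 9/13 = 69.2% < 75%
  expect_equal(sort(rep4$failing_levels), sort(cal$nominal_conc[c(5, 8, 11, 12)]))
})

test_that("acceptance is monotone in added bias", {
  cal <- make_line_calibrators()
  curve <- fit_calibration(cal)
  set.seed(18)
  for (rep in 1:20) {
    k <- sample(0:13, 1)
    idx <- sample(13, k)
    pert <- cal
    pert$ratio[idx] <- pert$ratio[idx] * stats::runif(k, 1.3, 2)
    before <- validate_curve(curve, pert)
    worse <- pert
    j <- sample(13, 1)
    worse$ratio[j] <- worse$ratio[j] * 1.5
    after <- validate_curve(curve, worse)
    expect_lte(after$n_pass, before$n_pass)
    if (!before$accepted) expect_false(after$accepted)
  }
})

test_that("limits follow the bias rule and the 3.3 sigma/slope convention", {
  cal <- make_line_calibrators()
  curve <- fit_calibration(cal)
  limits <- estimate_limits(cal, curve)
  expect_equal(limits[["lloq"]], min(cal$nominal_conc))
  expect_lt(limits[["llod"]], limits[["lloq"]])
  # +25% bias at the lowest level pushes the LLOQ to the second level
  pert <- cal
  pert$ratio[1] <- pert$ratio[1] * 1.25
  expect_equal(estimate_limits(pert, curve)[["lloq"]], cal$nominal_conc[2])
  # LLOD is linear in sigma
  l1 <- estimate_limits(cal, curve, sigma = 0.004)[["llod"]]
  l2 <- estimate_limits(cal, curve, sigma = 0.008)[["llod"]]
  expect_equal(l2, 2 * l1)
  expect_equal(l1, 3.3 * 0.004 / curve$slope)
  # nothing qualifies -> NaN with a warning
  allbad <- cal
  allbad$ratio <- allbad$ratio * 2
  expect_warning(lim <- estimate_limits(allbad, curve), "flagged")
  expect_true(is.nan(lim[["lloq"]]))
})

test_that("quantification recovers QC nominals exactly on noise-free runs", {
  spec <- targeted_panel_spec(n_case = 4, n_control = 4, ratio_cv = 0,
                              is_area_cv = 0)
  run <- generate_targeted_run(spec, 20)
  curves <- lapply(split(run, run$analyte), function(d)
    fit_calibration(d[d$record_type == "calibrator", ], analyte = d$analyte[1]))
  conc <- quantify(run, curves)
  expect_equal(sort(unique(conc$analyte)),
               sort(c("inosine", "uridine", "phenylalanine", "threonine")))
  qc <- merge(conc[conc$record_type == "qc", ],
              run[run$record_type == "qc", c("sample_id", "analyte",
                                             "nominal_conc")],
              by = c("sample_id", "analyte"))
  expect_equal(qc$conc, qc$nominal_conc, tolerance = 1e-9)
})

test_that("subject concentrations are recovered within the noise budget", {
  run <- generate_targeted_run(targeted_panel_spec(n_case = 60,
                                                   n_control = 40), 21)
  curves <- lapply(split(run, run$analyte), function(d)
    fit_calibration(d[d$record_type == "calibrator", ], analyte = d$analyte[1]))
  conc <- quantify(run, curves)
  m <- merge(conc[conc$record_type == "subject", ], attr(run, "truth"),
             by = c("sample_id", "analyte"))
  expect_lte(stats::median(abs(m$conc - m$true_conc) / m$true_conc), 0.07)
})

test_that("missing internal standards and rejected curves are handled", {
  run <- generate_targeted_run(targeted_panel_spec(n_case = 3,
                                                   n_control = 3), 22)
  curves <- lapply(split(run, run$analyte), function(d)
    fit_calibration(d[d$record_type == "calibrator", ], analyte = d$analyte[1]))
  run$is_area[run$record_type == "subject" & run$sample_id == "S001" &
                run$analyte == "inosine"] <- 0
  conc <- quantify(run, curves)
  bad <- conc[conc$sample_id == "S001" & conc$analyte == "inosine", ]
  expect_true(is.na(bad$conc))
  expect_equal(bad$flag, "missing_is")
  curves$uridine$accepted <- FALSE
  expect_error(quantify(run, curves), "rejected")
  # dilution factor scales reported concentrations
  curves$uridine$accepted <- TRUE
  conc4 <- quantify(run, curves, dilution_factor = 4)
  ok <- !is.na(conc$conc)
  expect_equal(conc4$conc[ok], 4 * conc$conc[ok])
})
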