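test_that("missing values are imputed with 1/10 of the feature minimum", {
  x <- cbind(f1 = c(50, NA, 20, 80), f2 = c(1, 2, 3, 4))
  ft <- make_toy_table(x)
  out <- impute_missing(ft)
  expect_equal(out$intensities[, "f1"], c(50, 2.0, 20, 80),
               ignore_attr = TRUE)
  expect_equal(out$intensities[, "f2"], c(1, 2, 3, 4), ignore_attr = TRUE)
  # no missing entries: identity
  expect_equal(impute_missing(out)$intensities, out$intensities)
})

test_that("imputation equals min(present)/10 on randomized tables", {
  set.seed(21)
  for (rep in 1:10) {
    x <- matrix(stats::rexp(20 * 8, 0.01), 20, 8,
                dimnames = list(NULL, paste0("f", 1:8)))
    x[sample(length(x), 25)] <- NA
    out <- impute_missing(make_toy_table(x))$intensities
    for (j in seq_len(ncol(x))) {
      mn <- min(x[, j], na.rm = TRUE)  # independent scan
      expect_equal(unname(out[is.na(x[, j]), j]),
                   rep(mn / 10, sum(is.na(x[, j]))))
      expect_equal(unname(out[!is.na(x[, j]), j]),
                   unname(x[!is.na(x[, j]), j]))
    }
  }
})

test_that("features with no observed values are dropped with a warning", {
  x <- cbind(f1 = c(1, 2, 3), f2 = c(NA_real_, NA, NA))
  expect_warning(out <- impute_missing(make_toy_table(x)), "f2")
  expect_equal(colnames(out$intensities), "f1")
})

test_that("feature_rsd is sd/mean with scale invariance", {
  expect_equal(feature_rsd(c(100, 100, 100)), 0)
  expect_equal(feature_rsd(c(90, 110)), sqrt(200) / 100)
  v <- c(3, 7, 9, 4)
  expect_equal(feature_rsd(17.3 * v), feature_rsd(v))
  expect_error(feature_rsd(5), "at least 2")
  expect_error(feature_rsd(c(-1, 1)), "zero mean")
})

test_that("QC trend fitters reproduce constant and linear profiles", {
  for (method in c("loess_like", "ensemble_regression")) {
    tm <- fit_qc_trend(rep(1000, 4), c(1, 11, 21, 31), method, seed = 2)
    expect_equal(predict_trend(tm, 1:31), rep(1000, 31), tolerance = 1e-9)
    expect_equal(tm$reference_level, 1000)

    orders <- c(1, 8, 15, 22, 29, 36, 43, 50)
    line <- 1000 - 5 * orders
    tm <- fit_qc_trend(line, orders, method, seed = 2)
    pred <- predict_trend(tm, 1:50)
    expect_true(all(abs(pred - (1000 - 5 * (1:50))) / (1000 - 5 * (1:50))
                    < 0.01))
  }
  # seed-fixed ensemble is deterministic
  tm1 <- fit_qc_trend(c(900, 800, 950, 700), c(1, 10, 20, 30),
                      "ensemble_regression", seed = 5)
  tm2 <- fit_qc_trend(c(900, 800, 950, 700), c(1, 10, 20, 30),
                      "ensemble_regression", seed = 5)
  expect_identical(tm1, tm2)
  expect_error(fit_qc_trend(c(1, 2), c(1, 2), "ensemble_regression"),
               "global-median")
  expect_error(fit_qc_trend(c(0, 2, 3), c(1, 2, 3)), "positive")
})

test_that("trend predictions are clamped outside the QC order range", {
  tm <- fit_qc_trend(c(1000, 500), c(5, 25), "loess_like")
  expect_equal(predict_trend(tm, c(1, 5)), c(1000, 1000))
  expect_equal(predict_trend(tm, c(25, 40)), c(500, 500))
})

test_that("hand-computed toy: correction divides by the interpolated trend", {
  # QCs 1000 at order 1 and 500 at order 21; subject raw 600 at order 11;
  # linear interpolation gives trend(11) = 750, reference = median = 750
  x <- cbind(f1 = c(1000, 600, 500))
  ft <- make_toy_table(x, orders = c(1, 11, 21),
                       roles = c("qc", "subject", "qc"),
                       groups = c(NA, "case", NA))
  res <- correct_drift(ft, "loess_like")
  expect_equal(unname(res$table$intensities[2, 1]), 600 * 750 / 750)
  expect_equal(unname(res$table$intensities[1, 1]), 1000 * 750 / 1000)
  expect_equal(res$qc_report$corrected, "yes")
})

test_that("drift-free table is returned essentially unchanged", {
  set.seed(8)
  n <- 24
  roles <- rep("subject", n)
  roles[c(1, 8, 16, 24)] <- "qc"
  x <- matrix(stats::rexp(n * 6, 0.001), n, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  x[roles == "qc", ] <- 5000  # constant QCs
  ft <- make_toy_table(x, roles = roles,
                       groups = ifelse(roles == "qc", NA, "case"))
  res <- correct_drift(ft, "loess_like")
  expect_lt(max(abs(res$table$intensities / x - 1)), 1e-6)
})

test_that("correction flattens a synthetic monotone drift", {
  spec <- cohort_spec(n_case = 25, n_control = 25, n_features = 40,
                      n_planted = 0, cv_noise = 0.05, drift_amplitude = 0.5,
                      drift_shape = "linear", missing_rate = 0)
  ft <- generate_untargeted_cohort(spec, 31)
  for (method in c("loess_like", "ensemble_regression")) {
    res <- correct_drift(impute_missing(ft), method, seed = 1)
    qr <- res$qc_report
    expect_true(all(qr$corrected == "yes"))
    expect_true(all(qr$rsd_after < qr$rsd_before))
    expect_true(all(qr$rsd_after < 0.15))
  }
})

test_that("correction shrinks the error against the undrifted truth", {
  spec <- cohort_spec(n_case = 30, n_control = 30, n_features = 30,
                      n_planted = 0, cv_noise = 0.1, drift_amplitude = 0.4,
                      drift_shape = "exponential_decay", missing_rate = 0)
  ft <- generate_untargeted_cohort(spec, 17)
  truth <- attr(ft, "truth")
  sub <- ft$metadata$role == "subject"
  drift_mat <- outer(truth$drift[ft$metadata$injection_order],
                     truth$sensitivity, `^`)
  undrifted <- ft$intensities / drift_mat
  res <- correct_drift(impute_missing(ft), "loess_like")
  # correction restores values up to the per-feature QC reference scale, so
  # compare after per-feature median rescaling
  rel_err <- function(m) {
    m <- sweep(m[sub, ], 2, apply(m[sub, ], 2, stats::median), "/")
    u <- sweep(undrifted[sub, ], 2,
               apply(undrifted[sub, ], 2, stats::median), "/")
    abs(m / u - 1)
  }
  expect_lt(stats::median(rel_err(res$table$intensities)),
            stats::median(rel_err(ft$intensities)))
})

test_that("correction rescales per injection, preserving within-injection structure", {
  spec <- cohort_spec(n_case = 10, n_control = 10, n_features = 8,
                      n_planted = 0, cv_noise = 0.2, drift_amplitude = 0.3,
                      drift_shape = "linear", missing_rate = 0)
  ft <- generate_untargeted_cohort(spec, 13)
  res <- correct_drift(impute_missing(ft), "loess_like")
  factor <- res$table$intensities / ft$intensities
  # the correction factor depends only on (injection, feature), never on the
  # measured value: recompute it independently from the fitted trends
  trends <- fit_qc_trends(impute_missing(ft), "loess_like")
  ref <- attr(trends, "reference_levels")
  for (j in which(res$qc_report$corrected == "yes")) {
    expected <- ref[j] / predict_trend(trends[[1]][[j]],
                                       ft$metadata$injection_order)
    expect_equal(unname(factor[, j]), unname(expected), tolerance = 1e-12)
  }
})

test_that("per-batch correction harmonizes batch offsets", {
  spec <- cohort_spec(n_case = 30, n_control = 30, n_features = 12,
                      n_planted = 0, cv_noise = 0.05, drift_amplitude = 0.3,
                      drift_shape = "linear", n_batches = 2, batch_sd = 0.5,
                      missing_rate = 0)
  ft <- generate_untargeted_cohort(spec, 23)
  res <- correct_drift(impute_missing(ft), "loess_like")
  qr <- res$qc_report
  expect_true(all(qr$rsd_after <= qr$rsd_before + 1e-9))
  # QC medians per batch agree after correction
  md <- res$table$metadata
  qc1 <- res$table$intensities[md$role == "qc" & md$batch == 1, ]
  qc2 <- res$table$intensities[md$role == "qc" & md$batch == 2, ]
  ok <- qr$corrected == "yes"
  rel <- abs(apply(qc1, 2, stats::median) / apply(qc2, 2, stats::median) - 1)
  expect_lt(stats::median(rel[ok]), 0.05)
})
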