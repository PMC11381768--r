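test_that("confusion metrics count the positive (case) class correctly", {
  y <- rep(c(1, -1), c(6, 4))
  expect_equal(confusion_metrics(y, y),
               list(tp = 6, fp = 0, tn = 4, fn = 0, accuracy = 1,
                    sensitivity = 1, specificity = 1))
  # TP=2 FP=1 TN=3 FN=4
  y_true <- c(1, 1, 1, 1, 1, 1, -1, -1, -1, -1)
  y_pred <- c(1, 1, -1, -1, -1, -1, 1, -1, -1, -1)
  cm <- confusion_metrics(y_true, y_pred)
  expect_equal(cm$accuracy, 0.5)
  expect_equal(cm$sensitivity, 1 / 3)
  expect_equal(cm$specificity, 0.75)
  cm_all_pos <- confusion_metrics(y_true, rep(1, 10))
  expect_equal(cm_all_pos$sensitivity, 1)
  expect_equal(cm_all_pos$specificity, 0)
  expect_error(confusion_metrics(numeric(0), numeric(0)), "empty")
})

test_that("ROC handles the textbook 4-point example and separation", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(-1, -1, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(utils::tail(r$points$fpr, 1), 1)
  expect_equal(utils::tail(r$points$tpr, 1), 1)
  sep <- roc_auc(c(1, 2, 3, 10, 11), c(-1, -1, -1, 1, 1))
  expect_equal(sep$auc, 1)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("trapezoidal AUC equals the pairwise Mann-Whitney statistic", {
  set.seed(33)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    labels <- c(1, -1, sample(c(-1, 1), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # heavy ties
    expect_equal(roc_auc(scores, labels)$auc, auc_pairwise(scores, labels))
  }
})

test_that("AUC under independent scores is centred at 1/2", {
  set.seed(34)
  scores <- stats::rnorm(2000)
  labels <- sample(rep(c(1, -1), 1000))
  auc <- roc_auc(scores, labels)$auc
  # variance of the U-statistic AUC under the null
  se <- sqrt((2000 + 1) / (12 * 1000 * 1000))
  expect_lt(abs(auc - 0.5), 3 * se)
})

test_that("ROC agrees with an established implementation", {
  set.seed(35)
  scores <- stats::rnorm(60)
  labels <- sample(rep(c(1, -1), 30))
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                              direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(scores, labels)$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("PR curve matches hand enumeration and base-rate endpoints", {
  pr <- pr_curve(c(0.1, 0.4, 0.35, 0.8), c(-1, -1, 1, 1))
  # order by descending score: 0.8(+) 0.4(-) 0.35(+) 0.1(-)
  expect_equal(pr$points$recall, c(0.5, 0.5, 1, 1))
  expect_equal(pr$points$precision, c(1, 1 / 2, 2 / 3, 1 / 2))
  expect_true(all(diff(pr$points$recall) >= 0))
  expect_equal(pr$average_precision, 0.5 * 1 + 0.5 * 2 / 3)
  sep <- pr_curve(c(5, 6, 1, 2), c(1, 1, -1, -1))
  expect_true(all(sep$points$precision[sep$points$recall <= 1][1:2] == 1))
  # the all-called endpoint has recall 1 and precision = prevalence
  last <- nrow(pr$points)
  expect_equal(pr$points$recall[last], 1)
  expect_equal(pr$points$precision[last], 0.5)
  expect_error(pr_curve(1:3, rep(-1, 3)), "positive")
})

test_that("mean_ci follows the closed form and the sqrt(n) law", {
  expect_equal(unname(mean_ci(rep(0.7, 50))), c(0.7, 0.7, 0.7))
  v <- rep(c(0, 1), each = 1000)
  ci <- mean_ci(v)
  hw <- stats::qnorm(0.975) * stats::sd(v) / sqrt(2000)
  expect_equal(unname(ci), c(0.5, 0.5 - hw, 0.5 + hw))
  expect_equal(hw, 0.0219, tolerance = 1e-3)
  set.seed(36)
  x <- stats::rnorm(400)
  w1 <- diff(mean_ci(x)[c(2, 3)])
  w4 <- diff(mean_ci(rep(x, 4))[c(2, 3)])
  # width scales as sd/sqrt(n); the replicated vector's sample sd differs
  # from sd(x) only through the n-1 denominator
  expect_equal(unname(w1 / w4),
               2 * stats::sd(x) / stats::sd(rep(x, 4)), tolerance = 1e-12)
  expect_error(mean_ci(1), "n >= 2")
})

test_that("BH adjustment reproduces the step-up arithmetic", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(37)
  for (rep in 1:20) {
    p <- stats::runif(sample(3:50, 1))^2
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    for (q in c(0.01, 0.05, 0.2)) {
      expect_equal(adj <= q, bh_reject_bruteforce(p, q))
    }
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("group test is Welch's t with label antisymmetry", {
  set.seed(38)
  v <- c(stats::rnorm(20, 0), stats::rnorm(25, 1))
  g <- rep(c("a", "b"), c(20, 25))
  res <- group_difference_test(v, g)
  ref <- stats::t.test(v[g == "a"], v[g == "b"])
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  expect_equal(res$df, unname(ref$parameter))
  flipped <- group_difference_test(v, rep(c("b", "a"), c(20, 25)))
  expect_equal(flipped$statistic, -res$statistic)
  expect_equal(flipped$p_value, res$p_value)
  same <- group_difference_test(rep(c(1, 2), 10), rep(c("a", "b"), each = 10))
  expect_equal(same$p_value, 1)
  expect_error(group_difference_test(v, rep("a", 45)), "two levels")
})

test_that("simulated Welch rejection rate matches theoretical power", {
  set.seed(39)
  rej <- mean(replicate(1000, {
    group_difference_test(c(stats::rnorm(50, 0), stats::rnorm(50, 0.5)),
                          rep(c("a", "b"), each = 50))$p_value < 0.05
  }))
  pow <- stats::power.t.test(n = 50, delta = 0.5, sd = 1,
                             sig.level = 0.05)$power
  se <- sqrt(pow * (1 - pow) / 1000)
  expect_lt(abs(rej - pow), 3 * se + 0.01)
})

test_that("ratio analysis is degenerate-safe and scale-free", {
  set.seed(40)
  conc <- data.frame(sample_id = sprintf("S%02d", 1:40),
                     inosine = stats::rlnorm(40, 3, 0.4),
                     uridine = stats::rlnorm(40, 6, 0.4))
  outcome <- factor(rep(c("pCR", "non_pCR"), 20),
                    levels = c("pCR", "non_pCR"))
  # numerator == denominator: every ratio is 1, AUC exactly 1/2
  same <- data.frame(sample_id = conc$sample_id, inosine = conc$inosine,
                     uridine = conc$inosine)
  expect_equal(ratio_marker_analysis(same, "inosine", "uridine",
                                     outcome)$auc, 0.5)
  base <- ratio_marker_analysis(conc, "inosine", "uridine", outcome)
  scaled <- conc
  scaled$inosine <- 100 * conc$inosine
  scaled$uridine <- 100 * conc$uridine
  expect_equal(ratio_marker_analysis(scaled, "inosine", "uridine",
                                     outcome)$auc, base$auc)
  # a single-class stratum yields NA
  one_class <- ratio_marker_analysis(conc, "inosine", "uridine",
                                     factor(rep("pCR", 40),
                                            levels = c("pCR", "non_pCR")))
  expect_true(is.na(one_class$auc))
  bad <- conc
  bad$uridine[1] <- 0
  expect_warning(ratio_marker_analysis(bad, "inosine", "uridine", outcome),
                 "excluded")
})

test_that("a TNBC-only planted effect concentrates in the TNBC stratum", {
  deltas <- sapply(1:20, function(s) {
    nac <- generate_nac_cohort(nac_cohort_spec(effect_d = 1.2), 700 + s)
    res <- ratio_marker_analysis(
      nac$concentrations, "inosine", "uridine",
      factor(nac$metadata$response, levels = c("pCR", "non_pCR")),
      strata = nac$metadata$subtype)
    res$auc[res$stratum == "TNBC"] - max(res$auc[res$stratum != "TNBC"])
  })
  expect_gt(stats::median(deltas), 0)
})
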