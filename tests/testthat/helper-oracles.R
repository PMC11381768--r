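# Independent oracles used across the suite.  None of these share code with
# the package implementation paths they check.

# primal soft-margin objective for any (w, b)
svm_primal_objective <- function(w, b, x, y, cost) {
  0.5 * sum(w^2) + cost * sum(pmax(0, 1 - y * (drop(x %*% w) + b)))
}

# for a fixed w the primal is piecewise linear in b with breakpoints at
# y_i - w'x_i; the exact minimum over b is attained at one of them
svm_best_bias_objective <- function(w, x, y, cost) {
  s <- drop(x %*% w)
  min(vapply(y - s, function(b) svm_primal_objective(w, b, x, y, cost), 1))
}

# interior-point QP solve of the SVM dual (kernlab), independent of the
# package's SMO path; returns the primal objective after the exact bias
# line search, or Inf if the QP solver fails to converge
svm_qp_oracle <- function(x, y, cost) {
  n <- nrow(x)
  q <- tcrossprod(x) * tcrossprod(y)
  for (ridge in c(1e-8, 1e-6)) {
    sol <- tryCatch(
      kernlab::ipop(c = rep(-1, n), H = q + diag(ridge, n),
                    A = matrix(as.numeric(y), 1, n), b = 0, l = rep(0, n),
                    u = rep(cost, n), r = 0, sigf = 8, maxiter = 400),
      error = function(e) NULL)
    if (!is.null(sol)) {
      a <- pmin(pmax(kernlab::primal(sol), 0), cost)
      w <- drop(crossprod(x, a * y))
      return(svm_best_bias_objective(w, x, y, cost))
    }
  }
  Inf
}

# libsvm (e1071) at tight tolerance as a second independent solver
svm_libsvm_oracle <- function(x, y, cost) {
  sv <- suppressWarnings(e1071::svm(x, factor(y), kernel = "linear",
                                    cost = cost, scale = FALSE,
                                    tolerance = 1e-10))
  w <- drop(crossprod(sv$SV, sv$coefs))
  if (sv$labels[1] == -1) w <- -w
  svm_best_bias_objective(w, x, y, cost)
}

# brute-force AUC: fraction of (positive, negative) pairs ranked correctly,
# ties counted 1/2
auc_pairwise <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == -1]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# brute-force BH rejection set: largest k with p_(k) <= k * q / m
bh_reject_bruteforce <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ks <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(ks) > 0) rej[ord[seq_len(max(ks))]] <- TRUE
  rej
}

# weighted least squares by explicit normal equations (2x2 solve)
wls_normal_equations <- function(x, r, weighting_exponent) {
  w <- if (weighting_exponent == 0) rep(1, length(x)) else
    1 / x^weighting_exponent
  sw <- sum(w); swx <- sum(w * x); swxx <- sum(w * x^2)
  swr <- sum(w * r); swxr <- sum(w * x * r)
  sol <- solve(matrix(c(sw, swx, swx, swxx), 2, 2), c(swr, swxr))
  c(intercept = sol[1], slope = sol[2])
}

# two well-separated gaussian clusters (perfectly separable)
make_separated_data <- function(n_pos = 12, n_neg = 12, m = 3, gap = 10,
                                seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_pos * m, gap), n_pos, m),
             matrix(stats::rnorm(n_neg * m, -gap), n_neg, m))
  colnames(x) <- paste0("f", seq_len(m))
  list(x = x, y = rep(c(1L, -1L), c(n_pos, n_neg)))
}

# small feature table built by hand (no generator involvement)
make_toy_table <- function(intensities, orders = seq_len(nrow(intensities)),
                           roles = rep("subject", nrow(intensities)),
                           groups = NULL, batch = 1) {
  n <- nrow(intensities)
  if (is.null(groups)) groups <- ifelse(roles == "qc", NA, "case")
  feature_table(intensities,
                data.frame(sample_id = sprintf("T%02d", seq_len(n)),
                           role = roles, group = groups, cohort = "toy",
                           subtype = NA_character_, response = NA_character_,
                           injection_order = orders,
                           batch = rep(batch, length.out = n),
                           stringsAsFactors = FALSE))
}
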