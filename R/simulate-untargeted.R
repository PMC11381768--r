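#' Specification of a synthetic untargeted case-control cohort
#'
#' Defines the statistical structure of a simulated untargeted LC-MS
#' case-control cohort: cohort sizes, planted case-vs-control effects,
#' multiplicative noise, injection-order signal drift, batch offsets,
#' pooled-QC scheduling and below-detection censoring.  Defaults follow the
#' exploratory design the workflow targets: 200 cases vs 100 controls, 479
#' positive-mode features, a pooled QC before and after the sequence and
#' after every 10 subject injections.
#'
#' Intensities are generated as `exp(Normal)` so that multiplicative noise
#' and fold-changes compose additively on the log scale.  Drift is a shared
#' per-injection multiplier raised to a per-feature sensitivity exponent in
#' `[0.5, 1.5]`; pooled QCs are the per-feature mean of the subject true
#' signals, then subjected to the same drift and noise.  Missingness is
#' intensity censoring: values below a per-feature quantile are dropped,
#' mimicking below-detection loss rather than missing-completely-at-random.
#'
#' @param n_case,n_control subject counts per group.
#' @param n_features number of aligned features.
#' @param n_planted number of features carrying a case-vs-control effect.
#' @param planted_log2fc log2 fold-change (case vs control) of planted
#'   features.
#' @param base_log_mean natural-log intensity scale of a typical feature.
#' @param feature_log_sd between-feature spread of base abundances
#'   (natural-log scale).  The default 0 gives every feature the shared
#'   `base_log_mean` scale; positive values emulate heterogeneous feature
#'   abundances, under which weight-based importance is scale-confounded
#'   (see the methods vignette).
#' @param cv_noise multiplicative lognormal coefficient of variation applied
#'   to every measured intensity (biological + technical).
#' @param drift_amplitude maximal relative intensity loss across the run
#'   (0 = no drift).
#' @param drift_shape one of `"none"`, `"linear"`, `"exponential_decay"`,
#'   `"smooth_random"`.
#' @param n_batches number of contiguous analytical batches.
#' @param batch_sd log-scale SD of per-batch, per-feature offsets.
#' @param qc_every a pooled QC is injected after every `qc_every` subject
#'   injections (plus one before and one after the sequence).
#' @param missing_rate per-feature fraction of values censored below
#'   detection.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_case = 200, n_control = 100, n_features = 479,
                        n_planted = 10, planted_log2fc = 1.5,
                        base_log_mean = 11.5, feature_log_sd = 0,
                        cv_noise = 0.7, drift_amplitude = 0.3,
                        drift_shape = c("exponential_decay", "none", "linear",
                                        "smooth_random"),
                        n_batches = 1, batch_sd = 0, qc_every = 10,
                        missing_rate = 0.05) {
  drift_shape <- match.arg(drift_shape)
  spec <- list(n_case = n_case, n_control = n_control,
               n_features = n_features, n_planted = n_planted,
               planted_log2fc = planted_log2fc,
               base_log_mean = base_log_mean, feature_log_sd = feature_log_sd,
               cv_noise = cv_noise, drift_amplitude = drift_amplitude,
               drift_shape = drift_shape, n_batches = n_batches,
               batch_sd = batch_sd, qc_every = qc_every,
               missing_rate = missing_rate)
  counts <- c("n_case", "n_control", "n_features", "n_planted", "n_batches")
  for (f in counts) {
    v <- spec[[f]]
    if (length(v) != 1L || !is.finite(v) || v < 0 || v != round(v))
      stop(sprintf("%s must be a single non-negative integer", f))
  }
  if (spec$n_features < 1) stop("n_features must be >= 1")
  if (spec$n_batches < 1) stop("n_batches must be >= 1")
  if (spec$n_planted > spec$n_features)
    stop("n_planted must not exceed n_features")
  for (f in c("cv_noise", "drift_amplitude", "batch_sd", "missing_rate")) {
    v <- spec[[f]]
    if (length(v) != 1L || !is.finite(v) || v < 0 || v >= 1)
      stop(sprintf("%s must be a fraction in [0, 1)", f))
  }
  if (length(spec$qc_every) != 1L || spec$qc_every < 1 ||
      spec$qc_every != round(spec$qc_every))
    stop("qc_every must be an integer >= 1")
  if (!is.finite(spec$planted_log2fc)) stop("planted_log2fc must be finite")
  class(spec) <- "cohort_spec"
  spec
}

# shared per-injection drift multiplier, 1 at the start of the run
drift_curve <- function(n, amplitude, shape) {
  if (n == 1L || amplitude == 0 || shape == "none") return(rep(1, n))
  u <- (seq_len(n) - 1) / (n - 1)
  switch(shape,
         linear = 1 - amplitude * u,
         exponential_decay = (1 - amplitude) + amplitude * exp(-3 * u),
         smooth_random = {
           k <- 6L
           knots <- seq(0, 1, length.out = k)
           g <- stats::spline(knots, stats::rnorm(k), xout = u)$y
           rng <- range(g)
           if (diff(rng) < .Machine$double.eps) return(rep(1, n))
           (1 - amplitude) + amplitude * (g - rng[1]) / diff(rng)
         })
}

#' Generate a synthetic untargeted case-control cohort
#'
#' Simulates an untargeted feature table with interleaved pooled-QC
#' injections, planted case-vs-control log2 fold-changes, shared
#' injection-order drift, batch offsets, heteroscedastic multiplicative
#' noise and below-detection censoring.  Fully reproducible for a given
#' `(spec, seed)` pair.
#'
#' The returned table carries a `truth` attribute with the planted feature
#' ids, the drift curve and the per-feature drift sensitivities, so
#' downstream recovery can be scored against the generating model.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @param group_assignment optional character vector of length
#'   `n_case + n_control` with values `"case"`/`"control"` giving the
#'   subjects' group labels in acquisition order; used to generate paired
#'   ionization modes of one cohort (see [generate_two_mode_cohort()]).  By
#'   default the acquisition order of subjects is randomized.
#' @return A [feature_table()] with QC rows interleaved among randomized
#'   subject injections; attribute `truth` holds the generating ground
#'   truth.
#' @export
generate_untargeted_cohort <- function(spec, seed, group_assignment = NULL) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  set.seed(as.integer(seed))

  n_sub <- spec$n_case + spec$n_control
  if (n_sub < 1) stop("cohort must contain at least one subject")
  feature_ids <- sprintf("F%04d", seq_len(spec$n_features))
  mu <- spec$base_log_mean +
    stats::rnorm(spec$n_features, 0, spec$feature_log_sd)
  planted <- if (spec$n_planted > 0)
    sort(sample.int(spec$n_features, spec$n_planted)) else integer(0)

  # randomized acquisition order of subjects, QCs before/after the sequence
  # and after every qc_every subject injections
  if (is.null(group_assignment)) {
    group <- sample(rep(c("case", "control"), c(spec$n_case, spec$n_control)))
  } else {
    group <- group_assignment
    if (length(group) != n_sub ||
        sum(group == "case") != spec$n_case ||
        sum(group == "control") != spec$n_control)
      stop("group_assignment does not match the spec's group sizes")
  }
  roles <- c("qc")
  groups <- c(NA_character_)
  for (i in seq_len(n_sub)) {
    roles <- c(roles, "subject")
    groups <- c(groups, group[i])
    if (i %% spec$qc_every == 0 && i < n_sub) {
      roles <- c(roles, "qc")
      groups <- c(groups, NA_character_)
    }
  }
  roles <- c(roles, "qc")
  groups <- c(groups, NA_character_)
  n_inj <- length(roles)

  # expected (noise-free, drift-free) log signal per injection x feature
  delta <- spec$planted_log2fc * log(2)
  log_expected <- matrix(rep(mu, each = n_inj), n_inj, spec$n_features)
  is_case <- !is.na(groups) & groups == "case"
  log_expected[is_case, planted] <- log_expected[is_case, planted] + delta
  # pooled QC = per-feature mean of the subject true (natural-scale) signals
  sub_true <- exp(log_expected[roles == "subject", , drop = FALSE])
  qc_log <- log(colMeans(sub_true))
  log_expected[roles == "qc", ] <- matrix(rep(qc_log, each = sum(roles == "qc")),
                                          sum(roles == "qc"), spec$n_features)

  drift <- drift_curve(n_inj, spec$drift_amplitude, spec$drift_shape)
  sensitivity <- stats::runif(spec$n_features, 0.5, 1.5)
  log_drift <- outer(log(drift), sensitivity)

  batch <- rep(seq_len(spec$n_batches), length.out = n_inj,
               each = ceiling(n_inj / spec$n_batches))[seq_len(n_inj)]
  batch_off <- matrix(stats::rnorm(spec$n_batches * spec$n_features, 0,
                                   spec$batch_sd),
                      spec$n_batches, spec$n_features)

  sdlog <- sqrt(log(1 + spec$cv_noise^2))
  noise <- matrix(stats::rnorm(n_inj * spec$n_features, 0, sdlog),
                  n_inj, spec$n_features)
  intensities <- exp(log_expected + log_drift + batch_off[batch, , drop = FALSE] +
                       noise)

  if (spec$missing_rate > 0) {
    for (j in seq_len(spec$n_features)) {
      thr <- stats::quantile(intensities[, j], spec$missing_rate, names = FALSE)
      intensities[intensities[, j] < thr, j] <- NA_real_
    }
  }

  ids <- character(n_inj)
  ids[roles == "qc"] <- sprintf("QC%02d", seq_len(sum(roles == "qc")))
  ids[roles == "subject"] <- sprintf("S%03d", seq_len(n_sub))
  metadata <- data.frame(sample_id = ids, role = roles, group = groups,
                         cohort = "exploratory", subtype = NA_character_,
                         response = NA_character_,
                         injection_order = seq_len(n_inj), batch = batch,
                         stringsAsFactors = FALSE)
  colnames(intensities) <- feature_ids
  ft <- feature_table(intensities, metadata)
  attr(ft, "truth") <- list(planted = feature_ids[planted],
                            planted_idx = planted,
                            planted_log2fc = spec$planted_log2fc,
                            drift = drift, sensitivity = sensitivity,
                            spec = spec)
  ft
}

#' Generate paired two-mode feature tables for one cohort
#'
#' Simulates positive- and negative-ionization-mode feature tables of the
#' same subjects: the group labels and acquisition order are drawn once and
#' shared, while features, drift and noise are mode-specific.  The default
#' feature counts mirror a typical two-mode untargeted study (479 ESI+ and
#' 269 ESI- features).
#'
#' @param spec_pos,spec_neg [cohort_spec()]s for the two modes; their group
#'   sizes must agree.
#' @param seed integer seed.
#' @return Named list of two [feature_table()]s (`pos`, `neg`).
#' @export
generate_two_mode_cohort <- function(spec_pos = cohort_spec(),
                                     spec_neg = cohort_spec(n_features = 269),
                                     seed = 1) {
  if (spec_pos$n_case != spec_neg$n_case ||
      spec_pos$n_control != spec_neg$n_control)
    stop("both modes must share the cohort's group sizes")
  pos <- generate_untargeted_cohort(spec_pos, seed)
  grp <- pos$metadata$group[pos$metadata$role == "subject"]
  neg <- generate_untargeted_cohort(spec_neg, seed + 1L,
                                    group_assignment = grp)
  list(pos = pos, neg = neg)
}
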