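#' Workflow configuration
#'
#' Collects every tunable parameter of the three-phase workflow with the
#' protocol defaults: 2000 iterations of 4-fold CV for importance, 500 for
#' each top-N model up to N = 100, SVM cost 4 in discovery and 5 in targeted
#' validation, 1/x^2 calibration weighting.  Any unknown key is a hard error
#' -- silent typos corrupt reproducibility.
#'
#' @param ... overrides of the defaults listed by `default_config()`.
#' @return A named list of class `run_config`.
#' @export
pipeline_config <- function(...) {
  config <- default_config()
  overrides <- list(...)
  if (length(overrides) > 0 && (is.null(names(overrides)) ||
                                any(names(overrides) == "")))
    stop("all config entries must be named")
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  config[names(overrides)] <- overrides
  class(config) <- "run_config"
  config
}

#' @rdname pipeline_config
#' @export
default_config <- function() {
  list(folds = 4, n_iter_importance = 2000, n_iter_topn = 500, max_n = 100,
       c_discovery = 4, c_validation = 5, weighting_exponent = 2,
       tolerance = 0.01, trend_method = "loess_like",
       candidates_per_mode = 10, log_concentrations = FALSE,
       dilution_factor = 1, seed = 1)
}

# reproducible fingerprint of a config (no timestamps: reports from the same
# config + seed must be byte-identical)
provenance_block <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(unclass(config)))]), tmp)
  list(config_hash = unname(tools::md5sum(tmp)), seed = config$seed,
       package = "metabopanel",
       version = as.character(utils::packageVersion("metabopanel")))
}

prepare_mode <- function(ft, config) {
  n_in <- nrow(ft$intensities)
  imputed <- impute_missing(ft)
  corr <- correct_drift(imputed, method = config$trend_method,
                        seed = config$seed)
  sub <- subject_rows(corr$table)
  y <- ifelse(sub$metadata$group == "case", 1L, -1L)
  list(x = l2_normalize_rows(sub$intensities), y = y,
       sample_id = sub$metadata$sample_id, qc_report = corr$qc_report,
       counts = c(injections_in = n_in,
                  features_in = ncol(ft$intensities),
                  features_kept = ncol(corr$table$intensities),
                  subjects = nrow(sub$intensities)))
}

#' Discovery phase: drift-corrected feature table to minimal panel
#'
#' Runs the untargeted discovery pipeline: below-detection imputation,
#' pooled-QC drift correction, per-sample L2 normalization, repeated
#' stratified CV for squared-weight importance, importance ranking, the
#' progressive top-N accuracy curve and minimal-panel selection.
#'
#' With several ionization modes (a named list of feature tables), each mode
#' is processed and ranked independently; the top `candidates_per_mode`
#' features per mode are pooled, re-ranked on the concatenated
#' (per-mode-normalized) matrix, and the top-N curve is computed on the
#' pooled candidates.  Feature ids are prefixed with the mode name.
#'
#' @param tables a [feature_table()] or named list of them (one per ion
#'   mode).  Subject sets must coincide across modes.
#' @param config a [pipeline_config()].
#' @param availability_mask optional named logical; features marked `FALSE`
#'   (e.g. no chemical standard or unmatched MS/MS) are skipped before the
#'   top-N curve.
#' @return A list of class `discovery_report`: `panel`, `curve`, `cv` (per
#'   mode), `ranking` (pooled, availability-filtered), `qc_report` (per
#'   mode), `counts`, `provenance`.
#' @export
run_discovery <- function(tables, config = pipeline_config(),
                          availability_mask = NULL) {
  stopifnot(inherits(config, "run_config"))
  single <- inherits(tables, "feature_table")
  if (single) tables <- list(mode1 = tables)
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("multi-mode input must be a named list of feature tables")

  modes <- lapply(tables, prepare_mode, config = config)
  ref <- modes[[1]]
  for (m in modes) {
    if (!identical(m$sample_id, ref$sample_id) || !identical(m$y, ref$y))
      stop("subject samples and group labels must coincide across ion modes")
  }

  cvs <- list()
  rankings <- list()
  for (mode in names(modes)) {
    x <- modes[[mode]]$x
    if (!single) colnames(x) <- paste(mode, colnames(x), sep = ":")
    cv <- repeated_cv(x, modes[[mode]]$y, folds = config$folds,
                      n_iter = config$n_iter_importance,
                      c = config$c_discovery, seed = config$seed)
    cvs[[mode]] <- cv
    rankings[[mode]] <- rank_features(cv)
    modes[[mode]]$x <- x
  }

  if (single) {
    x_pool <- modes[[1]]$x
    ranking <- rankings[[1]]
  } else {
    candidates <- lapply(names(modes), function(mode)
      utils::head(rankings[[mode]], config$candidates_per_mode))
    x_pool <- do.call(cbind, lapply(modes, `[[`, "x"))
    x_pool <- x_pool[, unique(unlist(candidates)), drop = FALSE]
    pool_cv <- repeated_cv(x_pool, ref$y, folds = config$folds,
                           n_iter = config$n_iter_importance,
                           c = config$c_discovery, seed = config$seed)
    ranking <- rank_features(pool_cv)
  }
  if (!is.null(availability_mask)) {
    keep <- availability_mask[ranking]
    keep[is.na(keep)] <- FALSE
    ranking <- ranking[keep]
    if (length(ranking) == 0) stop("no features are available")
  }

  max_n <- min(config$max_n, length(ranking))
  curve <- topn_accuracy_curve(x_pool, ref$y, ranking, max_n = max_n,
                               folds = config$folds,
                               n_iter = config$n_iter_topn,
                               c = config$c_discovery, seed = config$seed)
  panel <- select_panel(curve, ranking, tolerance = config$tolerance)

  structure(list(panel = panel, curve = curve, cv = cvs, ranking = ranking,
                 qc_report = lapply(modes, `[[`, "qc_report"),
                 counts = lapply(modes, `[[`, "counts"),
                 provenance = provenance_block(config)),
            class = "discovery_report")
}

fit_cohort_curves <- function(run, config) {
  analytes <- unique(run$analyte)
  curves <- lapply(analytes, function(a) {
    cal <- run[run$analyte == a & run$record_type == "calibrator", ,
               drop = FALSE]
    fit_calibration(cal, weighting_exponent = config$weighting_exponent,
                    analyte = a)
  })
  names(curves) <- analytes
  rejected <- analytes[!vapply(curves, function(cv) isTRUE(cv$accepted), TRUE)]
  if (length(rejected) > 0) {
    cond <- structure(
      class = c("curve_rejected", "error", "condition"),
      list(message = paste0("calibration curve rejected for: ",
                            paste(rejected, collapse = ", ")),
           call = sys.call(-1), curves = curves))
    stop(cond)
  }
  curves
}

#' Targeted validation phase: calibrate, quantify, train and evaluate
#'
#' For each cohort, fits per-analyte calibration curves from that cohort's
#' own calibrators (each analytical run carries a fresh calibration),
#' quantifies the subjects, trains the diagnostic SVM (`c = c_validation`)
#' on the training cohort's per-sample L2-normalized concentrations, and
#' reports confusion metrics, ROC and precision-recall for every cohort.
#' A rejected calibration curve for any panel analyte aborts with a
#' `curve_rejected` condition carrying the curve report.
#'
#' @param runs named list of `targeted_run` data.frames; must include
#'   `training`, further cohorts (e.g. `test`, `validation`) are evaluated
#'   with the trained model.
#' @param config a [pipeline_config()].
#' @return A list of class `validation_report`: `model`, `curves` and
#'   per-cohort `cohorts[[name]]` with `concentrations`, `confusion`, `roc`,
#'   `pr`, plus `provenance`.
#' @export
run_validation <- function(runs, config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!"training" %in% names(runs)) stop("runs must include 'training'")

  cohorts <- list()
  curves <- list()
  conc_mats <- list()
  for (nm in names(runs)) {
    curves[[nm]] <- fit_cohort_curves(runs[[nm]], config)
    conc <- quantify(runs[[nm]], curves[[nm]],
                     dilution_factor = config$dilution_factor)
    cm <- concentration_matrix(conc, "subject")
    conc_mats[[nm]] <- cm
    cohorts[[nm]] <- list(concentrations = conc)
  }

  analyte_order <- colnames(conc_mats$training$x)
  featurize <- function(cm) {
    x <- cm$x[, analyte_order, drop = FALSE]
    if (config$log_concentrations) x <- log(x)
    l2_normalize_rows(x)
  }
  y_train <- ifelse(conc_mats$training$group == "case", 1L, -1L)
  model <- train_linear_svm(featurize(conc_mats$training), y_train,
                            c = config$c_validation, seed = config$seed)

  for (nm in names(runs)) {
    x <- featurize(conc_mats[[nm]])
    y <- ifelse(conc_mats[[nm]]$group == "case", 1L, -1L)
    scores <- decision_values(model, x)
    cohorts[[nm]]$confusion <- confusion_metrics(y, predict_svm(model, x))
    cohorts[[nm]]$roc <- roc_auc(scores, y)
    cohorts[[nm]]$pr <- pr_curve(scores, y)
  }

  structure(list(model = model, curves = curves, cohorts = cohorts,
                 provenance = provenance_block(config)),
            class = "validation_report")
}

#' NAC response phase: per-marker and ratio-marker analysis
#'
#' Tests each panel metabolite within each tumor subtype for a pCR vs
#' non-pCR difference (Welch's t on log concentrations), adjusts the whole
#' marker-by-subtype family by Benjamini-Hochberg, and reports per-cell ROC
#' AUCs plus the inosine/uridine ratio analysis per subtype.  AUCs are
#' oriented so that lower marker levels (and ratio) in responders give
#' values above 0.5, matching the direction of the planted biology.
#'
#' @param concentrations data.frame `sample_id` + one column per metabolite.
#' @param metadata data.frame with `sample_id`, `subtype`, `response`
#'   (`"pCR"` / `"non_pCR"`).
#' @param config a [pipeline_config()].
#' @param ratio_pair numerator/denominator metabolites for the ratio marker.
#' @param q FDR level used to flag significant cells.
#' @return A list of class `nac_report`: `markers` (marker x subtype table
#'   with `p_value`, `p_adjusted`, `auc`, `significant`), `ratio` (per
#'   subtype), `provenance`.
#' @export
run_nac <- function(concentrations, metadata, config = pipeline_config(),
                    ratio_pair = c("inosine", "uridine"), q = 0.05) {
  stopifnot(inherits(config, "run_config"))
  if (!all(c("subtype", "response") %in% names(metadata)) ||
      anyNA(metadata$subtype))
    stop("metadata must provide subtype and response labels")
  md <- metadata[match(concentrations$sample_id, metadata$sample_id), ]
  if (anyNA(md$sample_id)) stop("metadata is missing some samples")
  markers <- setdiff(names(concentrations), "sample_id")
  subtypes <- unique(md$subtype)

  cells <- expand.grid(marker = markers, subtype = subtypes,
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- md$subtype == cells$subtype[i]
    v <- concentrations[[cells$marker[i]]][sel]
    resp <- md$response[sel]
    n <- table(factor(resp, levels = c("pCR", "non_pCR")))
    out <- data.frame(marker = cells$marker[i], subtype = cells$subtype[i],
                      n_pcr = unname(n["pCR"]), n_non_pcr = unname(n["non_pCR"]),
                      p_value = NA_real_, auc = NA_real_,
                      stringsAsFactors = FALSE)
    if (all(n >= 2)) {
      out$p_value <- group_difference_test(log(v), resp)$p_value
      out$auc <- roc_auc(v, ifelse(resp == "non_pCR", 1, -1))$auc
    }
    out
  })
  markers_tab <- do.call(rbind, res)
  markers_tab$p_adjusted <- bh_adjust(markers_tab$p_value)
  markers_tab$significant <- !is.na(markers_tab$p_adjusted) &
    markers_tab$p_adjusted <= q

  ratio <- ratio_marker_analysis(
    concentrations, ratio_pair[1], ratio_pair[2],
    factor(md$response, levels = c("pCR", "non_pCR")), strata = md$subtype)

  structure(list(markers = markers_tab, ratio = ratio,
                 ratio_pair = ratio_pair, q = q,
                 provenance = provenance_block(config)),
            class = "nac_report")
}
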