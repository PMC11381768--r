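#' Specification of a synthetic neoadjuvant-chemotherapy (NAC) cohort
#'
#' Describes a cohort of breast-cancer patients treated with NAC, stratified
#' by molecular subtype (TNBC, HR+/HER2-, HER2+) with a pathological
#' complete response (pCR) outcome, and panel-metabolite plasma
#' concentrations.  A standardized mean difference `effect_d` on the log
#' concentration scale is planted only in `affected_markers` within
#' `affected_subtypes` (pCR group shifted downwards, matching the direction
#' in which responders differ).
#'
#' Log concentrations share a subject-level variance component equal in size
#' to the marker-specific component (between-marker correlation 0.5), so
#' common physiological variation partially cancels in metabolite ratios.
#' Under this model the expected ROC AUC of an affected marker (and of a
#' ratio of an affected to an unaffected marker) is the binormal closed form
#' `pnorm(effect_d / sqrt(2))`.
#'
#' @param sizes named list: per subtype, a length-2 vector
#'   `c(pCR = ..., non_pCR = ...)` of group sizes.  Default TNBC sizes are
#'   27 pCR / 25 non-pCR; the other subtypes use typical pCR rates.
#' @param effect_d standardized mean difference on log concentration.
#' @param affected_markers subset of the four panel metabolites.  The
#'   default plants the effect on inosine alone, so the inosine/uridine
#'   ratio keeps its signal while uridine cancels the shared subject-level
#'   variation (an identical shift on both markers would cancel in the
#'   ratio).
#' @param affected_subtypes subset of the subtypes in `sizes`.
#' @param markers data.frame with columns `name`, `logmean`, `logsd` for the
#'   panel metabolites (non-pCR scale).
#' @return A validated list of class `nac_cohort_spec`.
#' @export
nac_cohort_spec <- function(sizes = list("TNBC" = c(pCR = 27, non_pCR = 25),
                                         "HR+/HER2-" = c(pCR = 10, non_pCR = 30),
                                         "HER2+" = c(pCR = 15, non_pCR = 15)),
                            effect_d = 1.0,
                            affected_markers = "inosine",
                            affected_subtypes = "TNBC",
                            markers = default_nac_markers()) {
  if (!all(c("name", "logmean", "logsd") %in% names(markers)))
    stop("markers must have columns name, logmean, logsd")
  for (s in names(sizes)) {
    v <- sizes[[s]]
    if (length(v) != 2L || any(v < 0) || any(v != round(v)) ||
        !all(c("pCR", "non_pCR") %in% names(v)))
      stop("each subtype needs integer sizes c(pCR = ..., non_pCR = ...)")
  }
  if (!all(affected_markers %in% markers$name))
    stop("affected_markers must be panel metabolites")
  if (!all(affected_subtypes %in% names(sizes)))
    stop("affected_subtypes must appear in sizes")
  if (!is.finite(effect_d)) stop("effect_d must be finite")
  structure(list(sizes = sizes, effect_d = effect_d,
                 affected_markers = affected_markers,
                 affected_subtypes = affected_subtypes, markers = markers),
            class = "nac_cohort_spec")
}

#' @rdname nac_cohort_spec
#' @export
default_nac_markers <- function() {
  # a common log-scale sd makes marker noise exchangeable, so a planted
  # standardized effect d maps to the binormal AUC pnorm(d / sqrt(2)) for
  # affected markers and for ratios of an affected to an unaffected marker
  data.frame(name = c("inosine", "uridine", "phenylalanine", "threonine"),
             logmean = log(c(25, 550, 14000, 12500)),
             logsd = 0.4, stringsAsFactors = FALSE)
}

#' Generate a synthetic NAC cohort
#'
#' Emits a concentration table for the four panel metabolites with subtype
#' and pCR labels; the planted standardized effect is confined to
#' `affected_markers` x `affected_subtypes`.
#'
#' @param spec a [nac_cohort_spec()].
#' @param seed integer seed.
#' @return A list with `concentrations` (data.frame `sample_id` + one column
#'   per metabolite, ng/mL) and `metadata` (`sample_id`, `subtype`,
#'   `response`).
#' @export
generate_nac_cohort <- function(spec, seed) {
  if (!inherits(spec, "nac_cohort_spec")) stop("spec must be a nac_cohort_spec")
  set.seed(as.integer(seed))
  subtype <- unlist(lapply(names(spec$sizes), function(s)
    rep(s, sum(spec$sizes[[s]]))))
  response <- unlist(lapply(spec$sizes, function(v)
    rep(c("pCR", "non_pCR"), v[c("pCR", "non_pCR")])))
  n <- length(subtype)
  if (n == 0) stop("cohort is empty")
  sample_ids <- sprintf("N%03d", seq_len(n))

  shared <- stats::rnorm(n)  # subject-level factor, correlation 0.5
  conc <- sapply(seq_len(nrow(spec$markers)), function(k) {
    m <- spec$markers[k, ]
    mu <- rep(m$logmean, n)
    hit <- m$name %in% spec$affected_markers &
      subtype %in% spec$affected_subtypes & response == "pCR"
    mu[hit] <- mu[hit] - spec$effect_d * m$logsd
    eps <- stats::rnorm(n)
    exp(mu + m$logsd * (shared + eps) / sqrt(2))
  })
  colnames(conc) <- spec$markers$name
  concentrations <- data.frame(sample_id = sample_ids, conc,
                               check.names = FALSE, stringsAsFactors = FALSE)
  metadata <- data.frame(sample_id = sample_ids, subtype = subtype,
                         response = response, stringsAsFactors = FALSE)
  rownames(concentrations) <- rownames(metadata) <- NULL
  list(concentrations = concentrations, metadata = metadata)
}
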