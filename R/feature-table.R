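#' Feature table container
#'
#' An untargeted LC-MS feature table: an injections-by-features intensity
#' matrix plus per-injection metadata.  Rows are injections in acquisition
#' order (subjects and pooled QCs interleaved); columns are aligned features.
#' Missing (below-detection) intensities are `NA`.
#'
#' @param intensities numeric matrix, injections x features, non-negative
#'   where present, with row names = sample ids and column names = feature
#'   ids.
#' @param metadata data.frame with one row per injection and columns
#'   `sample_id`, `role` (`"subject"` or `"qc"`), `group` (`"case"`,
#'   `"control"` or `NA`), `cohort`, `subtype`, `response`,
#'   `injection_order` (1-based, unique within `batch`), `batch`.
#' @return An object of class `feature_table`: a list with elements
#'   `intensities` and `metadata`.
#' @export
feature_table <- function(intensities, metadata) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("intensities must be a numeric matrix")
  required <- c("sample_id", "role", "group", "cohort", "subtype",
                "response", "injection_order", "batch")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols) > 0)
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(metadata) != nrow(intensities))
    stop("metadata rows must match intensity rows")
  if (anyDuplicated(metadata$sample_id) > 0)
    stop("duplicate sample ids")
  if (is.null(colnames(intensities)))
    colnames(intensities) <- sprintf("F%04d", seq_len(ncol(intensities)))
  if (anyDuplicated(colnames(intensities)) > 0)
    stop("duplicate feature ids")
  if (any(intensities < 0, na.rm = TRUE))
    stop("intensities must be non-negative where present")
  if (!all(metadata$role %in% c("subject", "qc")))
    stop("role must be 'subject' or 'qc'")
  ord <- split(metadata$injection_order, metadata$batch)
  if (any(vapply(ord, anyDuplicated, 1L) > 0))
    stop("injection_order must be unique within a batch")
  rownames(intensities) <- metadata$sample_id
  structure(list(intensities = intensities, metadata = metadata),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "feature_table: %d injections x %d features (%d subject, %d QC; %d batch%s)\n",
    nrow(x$intensities), ncol(x$intensities), sum(md$role == "subject"),
    sum(md$role == "qc"), length(unique(md$batch)),
    if (length(unique(md$batch)) == 1L) "" else "es"))
  n_missing <- sum(is.na(x$intensities))
  cat(sprintf("  missing entries: %d (%.2f%%)\n", n_missing,
              100 * n_missing / length(x$intensities)))
  invisible(x)
}

#' Number of injections / features
#' @param x a `feature_table`
#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Write / read a feature table as TSV
#'
#' The intensity table is written with a `sample_id` key column followed by
#' one column per feature (missing values as `NA`); the metadata table holds
#' the injection annotations.  `read_feature_table()` reverses the pair.
#'
#' @param x a `feature_table`
#' @param table_path path for the intensity TSV
#' @param metadata_path path for the metadata TSV
#' @return `write_feature_table()` returns its input invisibly;
#'   `read_feature_table()` returns a `feature_table`.
#' @export
write_feature_table <- function(x, table_path, metadata_path) {
  stopifnot(inherits(x, "feature_table"))
  tab <- data.frame(sample_id = rownames(x$intensities),
                    as.data.frame(x$intensities, check.names = FALSE),
                    check.names = FALSE)
  utils::write.table(tab, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(table_path, metadata_path) {
  tab <- utils::read.delim(table_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  md <- utils::read.delim(metadata_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  intensities <- as.matrix(tab[, -1, drop = FALSE])
  rownames(intensities) <- tab$sample_id
  md$sample_id <- as.character(md$sample_id)
  feature_table(intensities, md[match(tab$sample_id, md$sample_id), ])
}

# subject-only view used by the discovery stage
subject_rows <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  keep <- x$metadata$role == "subject"
  list(intensities = x$intensities[keep, , drop = FALSE],
       metadata = x$metadata[keep, , drop = FALSE])
}
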