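#' Cohort table constructor
#'
#' Bundles a subjects-by-features numeric matrix (missing entries as `NA`)
#' with per-feature metadata into a `cohort_table` object, the raw analytic
#' substrate for all downstream preprocessing and modelling.
#'
#' @param values Numeric matrix, one row per subject, one column per feature.
#'   `NA` marks missing measurements.
#' @param subject_ids Character vector of unique subject identifiers, one per
#'   row. Defaults to the rownames of `values`.
#' @param feature_meta Data frame of per-feature metadata with columns
#'   `name`, `domain_tag`, `timepoint`, `log_transform`, `lod`, `is_binary`
#'   (and optionally `exclude` for derived/outcome variables that must not
#'   enter the clustering roster). Rows align with the columns of `values`.
#'
#' @return An object of class `cohort_table`: a list with elements `values`,
#'   `subject_ids`, `feature_meta`.
#' @export
cohort_table <- function(values, subject_ids = rownames(values), feature_meta) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(subject_ids)) {
    subject_ids <- paste0("S", seq_len(nrow(values)))
  }
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != nrow(values)) {
    stop("one subject id per row required")
  }
  if (anyDuplicated(subject_ids)) {
    stop("subject ids must be unique")
  }
  feature_meta <- validate_feature_meta(feature_meta, ncol(values))
  rownames(values) <- subject_ids
  colnames(values) <- feature_meta$name
  structure(
    list(values = values, subject_ids = subject_ids, feature_meta = feature_meta),
    class = "cohort_table"
  )
}

validate_feature_meta <- function(meta, n_features) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("name", "domain_tag", "timepoint", "log_transform", "lod", "is_binary")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("feature_meta lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(meta) != n_features) {
    stop("feature_meta must have one row per feature column")
  }
  if (anyDuplicated(meta$name)) {
    stop("feature names must be unique")
  }
  allowed <- c("antibody", "cytokine_protein", "cytokine_mrna",
               "infection", "demographic", "clinical")
  bad <- setdiff(unique(meta$domain_tag), allowed)
  if (length(bad)) {
    stop("unknown domain_tag: ", paste(bad, collapse = ", "))
  }
  has_lod <- !is.na(meta$lod)
  if (any(has_lod & meta$domain_tag != "antibody")) {
    stop("lod is only meaningful for antibody-class features")
  }
  if (any(has_lod & meta$lod <= 0)) {
    stop("lod must be positive")
  }
  if (is.null(meta$exclude)) meta$exclude <- FALSE
  meta$log_transform <- as.logical(meta$log_transform)
  meta$is_binary <- as.logical(meta$is_binary)
  meta$exclude <- as.logical(meta$exclude)
  rownames(meta) <- NULL
  meta
}

#' @export
print.cohort_table <- function(x, ...) {
  nmiss <- sum(is.na(x$values))
  cat(sprintf(
    "<cohort_table> %d subjects x %d features (%d missing entries, %.1f%%)\n",
    nrow(x$values), ncol(x$values), nmiss,
    100 * nmiss / max(1L, length(x$values))
  ))
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$values)

#' Subset a cohort table by subjects and/or features
#'
#' @param table A `cohort_table`.
#' @param subjects Row index (integer, logical, or subject-id character).
#' @param features Column index (integer, logical, or feature-name character).
#' @return A `cohort_table` restricted to the selection, metadata kept in step.
#' @export
subset_cohort <- function(table, subjects = NULL, features = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  v <- table$values
  meta <- table$feature_meta
  if (!is.null(features)) {
    if (is.character(features)) features <- match(features, meta$name)
    v <- v[, features, drop = FALSE]
    meta <- meta[features, , drop = FALSE]
  }
  if (!is.null(subjects)) {
    if (is.character(subjects)) subjects <- match(subjects, table$subject_ids)
    v <- v[subjects, , drop = FALSE]
  }
  cohort_table(v, rownames(v), meta)
}

#' Read a cohort CSV and its feature-metadata CSV
#'
#' The cohort CSV has the subject id in the first column, a header row of
#' feature names, and `NA` or empty cells for missing values. The metadata
#' CSV has columns `name,domain_tag,timepoint,log_transform,lod,is_binary`
#' (plus optional `exclude`); features are matched to cohort columns by name.
#'
#' @param cohort_csv Path to the subjects-by-features CSV.
#' @param meta_csv Path to the feature-metadata CSV.
#' @return A `cohort_table`.
#' @export
read_cohort_csv <- function(cohort_csv, meta_csv) {
  raw <- utils::read.csv(cohort_csv, check.names = FALSE,
                         na.strings = c("NA", ""), stringsAsFactors = FALSE)
  ids <- as.character(raw[[1L]])
  values <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  meta <- utils::read.csv(meta_csv, na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  ord <- match(colnames(values), meta$name)
  if (anyNA(ord)) {
    stop("features missing from metadata: ",
         paste(colnames(values)[is.na(ord)], collapse = ", "))
  }
  cohort_table(values, ids, meta[ord, , drop = FALSE])
}

#' Write a cohort table to CSV (values + metadata sidecar)
#'
#' @param table A `cohort_table`.
#' @param cohort_csv Output path for the values CSV (first column
#'   `subject_id`).
#' @param meta_csv Optional output path for the feature-metadata CSV.
#' @return Invisibly, the cohort path.
#' @export
write_cohort_csv <- function(table, cohort_csv, meta_csv = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  df <- data.frame(subject_id = table$subject_ids, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, cohort_csv, row.names = FALSE)
  if (!is.null(meta_csv)) {
    utils::write.csv(table$feature_meta, meta_csv, row.names = FALSE)
  }
  invisible(cohort_csv)
}
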