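#' Remove features with excessive missingness
#'
#' Drops every feature whose missing fraction across subjects is strictly
#' greater than `max_missing_frac`; a feature missing in exactly that
#' fraction of subjects is kept. Feature order is preserved.
#'
#' @param table A `cohort_table`.
#' @param max_missing_frac Strict upper bound on per-feature missing
#'   fraction, in (0, 1). Default 0.20.
#' @return The filtered `cohort_table`.
#' @export
filter_features <- function(table, max_missing_frac = 0.20) {
  stopifnot(inherits(table, "cohort_table"))
  if (!(max_missing_frac > 0 && max_missing_frac < 1)) {
    stop("max_missing_frac must lie in (0, 1)")
  }
  frac <- colMeans(is.na(table$values))
  keep <- frac <= max_missing_frac
  if (!any(keep)) {
    stop("all features exceed the missingness threshold; table unusable")
  }
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message(sprintf("filter_features: removed %d of %d features (> %.0f%% missing)",
                    n_removed, length(keep), 100 * max_missing_frac))
  }
  subset_cohort(table, features = which(keep))
}

#' Remove subjects with excessive missingness
#'
#' Drops every subject whose missing fraction over the (already filtered)
#' feature set is strictly greater than `max_missing_frac`.
#'
#' @param table A `cohort_table`, features already filtered.
#' @param max_missing_frac Strict upper bound on per-subject missing
#'   fraction, in (0, 1). Default 0.30.
#' @return The filtered `cohort_table`.
#' @export
filter_subjects <- function(table, max_missing_frac = 0.30) {
  stopifnot(inherits(table, "cohort_table"))
  if (!(max_missing_frac > 0 && max_missing_frac < 1)) {
    stop("max_missing_frac must lie in (0, 1)")
  }
  frac <- rowMeans(is.na(table$values))
  keep <- frac <= max_missing_frac
  if (!any(keep)) {
    stop("all subjects exceed the missingness threshold; table unusable")
  }
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message(sprintf("filter_subjects: removed %d of %d subjects (> %.0f%% missing)",
                    n_removed, length(keep), 100 * max_missing_frac))
  }
  subset_cohort(table, subjects = which(keep))
}

#' Partition a filtered cohort into complete-case and low-missingness subsets
#'
#' Complete-case subjects have no missing values over the retained features
#' and train the mixture model; the low-missingness complement is classified
#' afterwards through the fitted densities.
#'
#' @param table A feature- and subject-filtered `cohort_table`.
#' @return A list with `cohort_table` elements `complete_case` and
#'   `low_missingness` (the latter possibly with zero subjects).
#' @export
split_complete_low_missing <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  complete <- rowSums(is.na(table$values)) == 0L
  if (!any(complete)) {
    stop("no complete-case subjects; cannot fit a model")
  }
  list(
    complete_case = subset_cohort(table, subjects = which(complete)),
    low_missingness = subset_cohort(table, subjects = which(!complete))
  )
}

#' Half-LOD substitution for left-censored assay values
#'
#' Immunoassay readings below the instrument's limit of detection are
#' replaced by half the LOD (e.g. IgE below 0.03 kU/L becomes 0.015 kU/L);
#' values at or above the LOD, and missing values, are untouched. The
#' operation is idempotent.
#'
#' @param values Numeric vector in native assay units (pre-log).
#' @param lod Positive limit of detection in the same units.
#' @return The substituted vector.
#' @export
substitute_lod <- function(values, lod) {
  if (!is.numeric(lod) || length(lod) != 1L || is.na(lod) || lod <= 0) {
    stop("lod must be a single positive number")
  }
  below <- !is.na(values) & values < lod
  values[below] <- lod / 2
  values
}

#' Floor substitution for non-positive cytokine net responses
#'
#' Stimulated-minus-control cytokine responses can be zero or negative when
#' the unstimulated control matches or exceeds the stimulated well; such
#' entries are set to a small positive floor (0.01 pg/ml for protein,
#' 0.000001 units for mRNA) so that the subsequent log10 transform is
#' defined.
#'
#' @param values Numeric vector of net responses.
#' @param floor_value Positive replacement for entries `<= 0`.
#' @return The substituted vector.
#' @export
substitute_nonpositive <- function(values, floor_value) {
  if (!is.numeric(floor_value) || length(floor_value) != 1L ||
      is.na(floor_value) || floor_value <= 0) {
    stop("floor_value must be a single positive number")
  }
  nonpos <- !is.na(values) & values <= 0
  values[nonpos] <- floor_value
  values
}

#' Base-10 log transform for skewed features
#'
#' @param values Numeric vector; all non-missing entries must be positive
#'   (guaranteed after LOD/floor substitution).
#' @param feature Optional feature name used in the error message.
#' @return `log10(values)`, missing entries preserved.
#' @export
log10_transform <- function(values, feature = "feature") {
  bad <- !is.na(values) & values <= 0
  if (any(bad)) {
    stop(sprintf("non-positive value in '%s'; apply LOD/floor substitution first",
                 feature))
  }
  log10(values)
}

# Default cytokine floors, in the assays' native units.
cytokine_floor <- function(domain_tag) {
  switch(domain_tag,
         cytokine_protein = 0.01,    # pg/ml
         cytokine_mrna = 0.000001,   # expression units
         stop("no floor defined for domain ", domain_tag))
}

#' Per-feature reference statistics from the complete-case matrix
#'
#' Median, minimum and maximum of every feature, computed once on the
#' complete-case (no missing values) training matrix and stored in the model
#' so that new data are always scaled against the same reference. For even
#' n the median is the midpoint of the two central order statistics.
#'
#' @param values Numeric matrix with no missing entries.
#' @return A data frame with columns `feature`, `median`, `min`, `max`.
#' @export
compute_reference_stats <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) {
    stop("reference statistics require a complete-case matrix")
  }
  med <- apply(values, 2L, stats::median)
  mn <- apply(values, 2L, min)
  mx <- apply(values, 2L, max)
  if (any(mx == mn)) {
    stop("zero-range feature(s): ",
         paste(colnames(values)[mx == mn], collapse = ", "),
         " (uninformative; drop before computing reference stats)")
  }
  data.frame(feature = colnames(values), median = med, min = mn, max = mx,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Positional standardisation scaling
#'
#' Replaces each value x_ij by (x_ij - med(x_j)) / (max(x_j) - min(x_j)),
#' where the median, maximum and minimum are the stored complete-case
#' reference statistics for feature j. On the training complete-case matrix
#' every scaled value lies in [-1, 1] and every column has median zero;
#' external values may fall outside [-1, 1] and are handled downstream by
#' density clipping. New data must be scaled with the model's stored stats,
#' never refit.
#'
#' @param values Numeric matrix (missing entries preserved) whose columns
#'   align with `stats$feature`.
#' @param ref_stats Reference statistics from [compute_reference_stats()].
#' @return The scaled matrix.
#' @export
positional_scale <- function(values, ref_stats) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    if (ncol(values) != nrow(ref_stats)) stop("column/stats mismatch")
  } else {
    if (!identical(colnames(values), ref_stats$feature)) {
      stop("matrix columns do not align with reference statistics")
    }
  }
  rng <- ref_stats$max - ref_stats$min
  sweep(sweep(values, 2L, ref_stats$median, "-"), 2L, rng, "/")
}

#' Invert positional standardisation scaling
#'
#' @param scaled Scaled matrix from [positional_scale()].
#' @param ref_stats The reference statistics used to scale.
#' @return The matrix in original (post-transform) units.
#' @export
positional_unscale <- function(scaled, ref_stats) {
  rng <- ref_stats$max - ref_stats$min
  sweep(sweep(as.matrix(scaled), 2L, rng, "*"), 2L, ref_stats$median, "+")
}

#' Full preprocessing pipeline for a raw cohort table
#'
#' Applies, in order: exclusion of metadata-flagged features (outcomes and
#' derived variables never enter the clustering roster), feature filtering
#' (missing fraction > `feature_thresh`), subject filtering (missing
#' fraction > `subject_thresh`), half-LOD substitution for antibody
#' features, floor substitution for cytokine net responses, base-10 log
#' transform of flagged features, removal of zero-range features,
#' complete-case / low-missingness partition, reference-statistic
#' computation on the complete-case subset, and positional standardisation
#' scaling of both subsets against those statistics. Missing values are
#' never imputed; they are carried through to the classifier.
#'
#' @param table A raw `cohort_table`.
#' @param feature_thresh Strict per-feature missingness bound (default 0.20).
#' @param subject_thresh Strict per-subject missingness bound (default 0.30).
#' @return A list: `complete_case` and `low_missingness` (scaled matrices),
#'   `ref_stats`, the filtered `cohort_table` (`filtered`), the
#'   complete-case / low-missingness `cohort_table`s in transformed units,
#'   and bookkeeping of removed features/subjects.
#' @export
preprocess_cohort <- function(table, feature_thresh = 0.20, subject_thresh = 0.30) {
  stopifnot(inherits(table, "cohort_table"))
  features_in <- table$feature_meta$name
  subjects_in <- table$subject_ids

  excl <- table$feature_meta$exclude
  if (any(excl)) table <- subset_cohort(table, features = which(!excl))

  table <- filter_features(table, feature_thresh)
  table <- filter_subjects(table, subject_thresh)

  v <- table$values
  meta <- table$feature_meta
  for (j in seq_len(ncol(v))) {
    if (!is.na(meta$lod[j])) {
      v[, j] <- substitute_lod(v[, j], meta$lod[j])
    }
    if (meta$domain_tag[j] %in% c("cytokine_protein", "cytokine_mrna")) {
      v[, j] <- substitute_nonpositive(v[, j], cytokine_floor(meta$domain_tag[j]))
    }
    if (meta$log_transform[j]) {
      v[, j] <- log10_transform(v[, j], meta$name[j])
    }
  }
  table <- cohort_table(v, table$subject_ids, meta)

  parts <- split_complete_low_missing(table)
  cc <- parts$complete_case

  rng <- apply(cc$values, 2L, function(col) diff(range(col)))
  if (any(rng == 0)) {
    message(sprintf("dropping %d zero-range feature(s): %s", sum(rng == 0),
                    paste(cc$feature_meta$name[rng == 0], collapse = ", ")))
    keep <- which(rng > 0)
    table <- subset_cohort(table, features = keep)
    parts <- split_complete_low_missing(table)
    cc <- parts$complete_case
  }

  ref_stats <- compute_reference_stats(cc$values)
  list(
    complete_case = positional_scale(cc$values, ref_stats),
    low_missingness = positional_scale(parts$low_missingness$values, ref_stats),
    ref_stats = ref_stats,
    filtered = table,
    complete_case_table = cc,
    low_missingness_table = parts$low_missingness,
    removed_features = setdiff(features_in, table$feature_meta$name),
    removed_subjects = setdiff(subjects_in, table$subject_ids)
  )
}
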