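#' Density evaluation with missing-value and out-of-range rules
#'
#' The classifier's density rule for one feature: a missing value
#' contributes a density of exactly 1 (so the feature drops out of the
#' posterior product); a value below the training support is assigned the
#' density of the support minimum; a value above it, the density of the
#' support maximum; anything in range is a plain KDE evaluation. Clipping
#' makes the posterior constant in each tail beyond the training range.
#'
#' @param kde A `wkde` from a fitted model (carries the training support).
#' @param x A single value, possibly `NA`.
#' @return A non-negative density value.
#' @export
density_clipped <- function(kde, x) {
  stopifnot(inherits(kde, "wkde"))
  if (is.na(x)) return(1.0)
  x <- min(max(x, kde$support[1L]), kde$support[2L])
  wkde_eval(kde, x)
}

# Vectorised clipped log-density contributions for one feature over many
# rows: returns an n x L matrix of log f_jk(x_i), rows with NA all zero.
feature_log_density <- function(model, j, x) {
  n <- length(x)
  out <- matrix(0, n, model$L)
  obs <- which(!is.na(x))
  if (!length(obs)) return(out)
  xo <- pmin(pmax(x[obs], model$support[j, 1L]), model$support[j, 2L])
  kmat <- stats::dnorm(outer(xo, model$train[, j], "-") / model$bandwidths[j]) /
    model$bandwidths[j]
  out[obs, ] <- log(pmax(kmat %*% model$weights, 1e-300))
  out
}

#' Posterior cluster probabilities for rows with arbitrary missingness
#'
#' For each subject, P(k | x) is proportional to
#' lambda_k * prod_{j observed} f_jk(x_j), with clipped densities and unit
#' density for missing features, computed in the log domain and normalised
#' over clusters. A row with every feature missing gets the prior
#' `lambdas` back. Rows must already be scaled with the model's stored
#' reference statistics.
#'
#' @param model A fitted `npem_model`.
#' @param rows A scaled matrix (or single row vector) whose columns match
#'   the model's features; `NA` marks missing.
#' @return An n x L posterior matrix, rows summing to 1.
#' @export
npem_posterior <- function(model, rows) {
  if (is.null(dim(rows))) {
    rows <- matrix(rows, nrow = 1L,
                   dimnames = list(NULL, model$feature_names))
  }
  rows <- align_model_columns(rows, model)
  logdens <- matrix(0, nrow(rows), model$L)
  for (j in seq_along(model$feature_names)) {
    logdens <- logdens + feature_log_density(model, j, rows[, j])
  }
  posterior_from_logs(logdens, model$lambdas)$posterior
}

#' Classify subjects into fitted clusters at a posterior threshold
#'
#' Each subject receives the argmax-posterior cluster if and only if the
#' maximum posterior strictly exceeds `threshold`; otherwise the subject is
#' left unclassified (`NA` label). Missing features contribute unit
#' densities, so subjects with arbitrary missingness can still be
#' classified on their observed features.
#'
#' @param model A fitted `npem_model`.
#' @param rows Scaled matrix of subjects to classify (columns match the
#'   model's features; `NA` for missing).
#' @param threshold Strict posterior threshold in `[0, 1)`; default 0.90.
#' @param subject_ids Optional ids; defaults to rownames.
#' @return A data frame with one row per subject: `subject_id`, `label`
#'   (integer or `NA`), `max_posterior`, `n_features_used`,
#'   `threshold_used`, and the L posterior columns `p1..pL`.
#' @export
npem_classify <- function(model, rows, threshold = 0.90, subject_ids = NULL) {
  if (!(is.numeric(threshold) && length(threshold) == 1L &&
        threshold >= 0 && threshold < 1)) {
    stop("threshold must lie in [0, 1)")
  }
  if (is.null(dim(rows))) {
    rows <- matrix(rows, nrow = 1L,
                   dimnames = list(NULL, model$feature_names))
  }
  if (is.null(subject_ids)) {
    subject_ids <- rownames(rows)
    if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(rows)))
  }
  post <- npem_posterior(model, rows)
  rows <- align_model_columns(rows, model)
  maxp <- apply(post, 1L, max)
  label <- max.col(post, ties.method = "first")
  label[maxp <= threshold] <- NA_integer_
  out <- data.frame(
    subject_id = subject_ids,
    label = as.integer(label),
    max_posterior = maxp,
    n_features_used = rowSums(!is.na(rows)),
    threshold_used = threshold,
    stringsAsFactors = FALSE
  )
  colnames(post) <- paste0("p", seq_len(model$L))
  cbind(out, as.data.frame(post))
}

#' Restrict a fitted model to a matched feature subset
#'
#' For cross-cohort classification, external features are matched to model
#' features; unmatched model features are removed (their densities act as
#' the constant 1, exactly as if the external subjects were missing those
#' values). Mixing proportions and per-(feature, cluster) densities of the
#' retained features are unchanged, so classification through the
#' restricted model is identical to classification through the full model
#' with unmatched features set missing.
#'
#' @param model A fitted `npem_model`.
#' @param features Character vector of model feature names to keep (for a
#'   mapping, the matched model-side names).
#' @return An `npem_model` over the retained features only.
#' @export
restrict_model <- function(model, features) {
  idx <- match(features, model$feature_names)
  if (anyNA(idx)) {
    stop("unknown model features: ",
         paste(features[is.na(idx)], collapse = ", "))
  }
  if (anyDuplicated(idx)) stop("feature mapping must be injective")
  if (!length(idx)) stop("zero matched features")
  out <- model
  out$train <- model$train[, idx, drop = FALSE]
  out$bandwidths <- model$bandwidths[idx]
  out$support <- model$support[idx, , drop = FALSE]
  out$feature_names <- model$feature_names[idx]
  if (!is.null(model$ref_stats)) {
    out$ref_stats <- model$ref_stats[match(out$feature_names,
                                           model$ref_stats$feature), ,
                                     drop = FALSE]
    rownames(out$ref_stats) <- NULL
  }
  out
}

#' Fraction of subjects assigned identical labels by two classifications
#'
#' Subjects unclassified in either assignment are excluded from the
#' denominator. Labels are compared as-is (both assignments share the
#' model's label space; no realignment).
#'
#' @param assign_a,assign_b Data frames from [npem_classify()] (need
#'   columns `subject_id`, `label`).
#' @return Concordance in `[0, 1]`.
#' @export
concordance <- function(assign_a, assign_b) {
  common <- intersect(assign_a$subject_id, assign_b$subject_id)
  if (!length(common)) stop("assignments share no subjects")
  la <- assign_a$label[match(common, assign_a$subject_id)]
  lb <- assign_b$label[match(common, assign_b$subject_id)]
  both <- !is.na(la) & !is.na(lb)
  if (!any(both)) stop("no subject classified in both assignments")
  mean(la[both] == lb[both])
}
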