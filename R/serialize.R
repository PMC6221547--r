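#' Serialize a fitted npEM model to JSON
#'
#' Writes everything needed to reproduce classification: L, mixing
#' proportions, the training sample points and per-cluster KDE weights,
#' bandwidths, support ranges, feature names, reference statistics, seed
#' and convergence record. The round trip through
#' [npem_model_from_json()] is lossless to full double precision.
#'
#' @param model A fitted `npem_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
npem_model_to_json <- function(model, path) {
  stopifnot(inherits(model, "npem_model"))
  payload <- list(
    L = model$L,
    lambdas = model$lambdas,
    feature_names = model$feature_names,
    train = model$train,
    weights = model$weights,
    bandwidths = model$bandwidths,
    support = model$support,
    ref_stats = model$ref_stats,
    final_loglik = model$final_loglik,
    n_iter = model$n_iter,
    converged = model$converged,
    seed = model$seed
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' Restore a fitted npEM model from JSON
#'
#' @param path Path written by [npem_model_to_json()].
#' @return An `npem_model`.
#' @export
npem_model_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  train <- as.matrix(p$train)
  colnames(train) <- p$feature_names
  weights <- as.matrix(p$weights)
  ref_stats <- if (is.null(p$ref_stats)) NULL else as.data.frame(p$ref_stats)
  # posterior[i, k] = weights[i, k] * (lambda_k * N), since the KDE weights
  # are the posterior columns normalised by their total mass
  post <- sweep(weights, 2L, as.numeric(p$lambdas) * nrow(weights), "*")
  structure(list(
    L = as.integer(p$L),
    lambdas = as.numeric(p$lambdas),
    weights = weights,
    train = train,
    bandwidths = as.numeric(p$bandwidths),
    support = as.matrix(p$support),
    feature_names = as.character(p$feature_names),
    posterior = post,
    ref_stats = ref_stats,
    final_loglik = as.numeric(p$final_loglik),
    n_iter = as.integer(p$n_iter),
    converged = as.logical(p$converged),
    seed = as.integer(p$seed)
  ), class = "npem_model")
}
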