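#' npEM fitting configuration
#'
#' @param L Number of mixture components (clusters), a positive integer.
#' @param seed Integer seed driving the k-means initialization; the fit is
#'   fully deterministic given (data, config).
#' @param max_iter Maximum number of EM iterations (default 500).
#' @param tol Convergence threshold on the posterior: iteration stops when
#'   the maximum absolute change in any posterior entry falls below `tol`
#'   (default 1e-6).
#' @param ll_tol Convergence threshold on the log-likelihood: iteration
#'   also stops when the absolute change in log-likelihood between
#'   successive iterations falls below `ll_tol` (default 1e-8). This is the
#'   primary stop in practice; it also guards against the slow component
#'   drift possible in low dimension, where the mixture likelihood is flat
#'   in the posteriors.
#' @return An object of class `npem_config`.
#' @export
npem_config <- function(L, seed = 1L, max_iter = 500L, tol = 1e-6,
                        ll_tol = 1e-8) {
  stopifnot(length(L) == 1L, L >= 1, L == round(L),
            length(seed) == 1L, is.finite(seed),
            max_iter >= 1, tol > 0, ll_tol >= 0)
  structure(list(L = as.integer(L), seed = as.integer(seed),
                 max_iter = as.integer(max_iter), tol = tol, ll_tol = ll_tol,
                 kernel = "gaussian", bandwidth_rule = "nrd0_constant"),
            class = "npem_config")
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Seeded k-means initialization for npEM
#'
#' Hard initial labels from k-means on the scaled complete-case matrix,
#' fully determined by (data, L, seed). Multiple seeded restarts
#' (`nstart`, default 10) guard against the poor local minima a single
#' random centroid draw can produce, which matters when one cluster is
#' small. If k-means returns an empty cluster the centroids are re-drawn
#' from the same seeded stream, up to a bounded number of retries.
#'
#' @param data Numeric matrix without missing entries, N >= L rows.
#' @param L Number of clusters.
#' @param seed Integer seed.
#' @param nstart Number of random centroid restarts (best of, by within-SS).
#' @param max_retries Bounded retries on an empty-cluster failure.
#' @return Integer labels in 1..L, every cluster non-empty.
#' @export
npem_init_kmeans <- function(data, L, seed = 1L, nstart = 10L,
                             max_retries = 10L) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("k-means initialization requires complete-case data")
  if (nrow(data) < L) stop("need at least L subjects")
  if (L == 1L) return(rep(1L, nrow(data)))
  with_seed(seed, {
    for (attempt in seq_len(max_retries)) {
      km <- tryCatch(stats::kmeans(data, centers = L, nstart = nstart),
                     error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(km) && all(tabulate(km$cluster, L) > 0L)) {
        return(as.integer(km$cluster))
      }
    }
    stop("k-means failed to produce L non-empty clusters after retries")
  })
}

#' Weighted KDEs for every (feature, cluster) pair
#'
#' For cluster k and feature j the density is a `wkde` over the pooled
#' training values of feature j, weighted by the k-th posterior column
#' normalised to sum to 1.
#'
#' @param data Scaled complete-case matrix (N x M).
#' @param posterior N x L posterior matrix, rows summing to 1.
#' @param bandwidths Length-M vector of per-feature bandwidths.
#' @return A list of length M; element j is a list of L `wkde` objects.
#' @export
npem_estimate_kdes <- function(data, posterior, bandwidths) {
  data <- as.matrix(data)
  posterior <- as.matrix(posterior)
  mass <- colSums(posterior)
  if (any(mass <= 0)) {
    stop("degenerate component: cluster ", which(mass <= 0)[1L],
         " has zero posterior mass")
  }
  lapply(seq_len(ncol(data)), function(j) {
    lapply(seq_len(ncol(posterior)), function(k) {
      wkde(data[, j], posterior[, k], bandwidths[j])
    })
  })
}

# Row-wise log-sum-exp with -Inf tolerance.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

# Per-feature kernel cross matrices: K[[j]][i, t] = phi((x_i - x_t)/h_j)/h_j
# evaluated between `eval` rows and `train` rows. Reused across EM
# iterations since sample points and bandwidths are fixed.
kernel_matrices <- function(eval, train, bandwidths) {
  lapply(seq_len(ncol(train)), function(j) {
    stats::dnorm(outer(eval[, j], train[, j], "-") / bandwidths[j]) / bandwidths[j]
  })
}

# Log component densities summed over features: out[i, k] =
# sum_j log f_jk(x_ij), with per-(i,j,k) densities floored at 1e-300.
log_component_density <- function(kmats, weights) {
  n <- nrow(kmats[[1L]])
  L <- ncol(weights)
  out <- matrix(0, n, L)
  for (j in seq_along(kmats)) {
    out <- out + log(pmax(kmats[[j]] %*% weights, 1e-300))
  }
  out
}

posterior_from_logs <- function(logdens, lambdas) {
  lp <- sweep(logdens, 2L, log(lambdas), "+")
  norm <- row_logsumexp(lp)
  post <- exp(lp - norm)
  post <- post / rowSums(post)
  dimnames(post) <- NULL
  list(posterior = post, loglik = sum(unname(norm)))
}

#' npEM E-step
#'
#' Posterior membership probabilities for complete-case rows: row i,
#' cluster k gets lambda_k * prod_j f_jk(x_ij), normalised over k.
#' Computed in log space to avoid underflow over many features.
#'
#' @param data Complete-case matrix aligned with the model's features.
#' @param model A fitted `npem_model`.
#' @return An N x L posterior matrix with rows summing to 1.
#' @export
npem_e_step <- function(data, model) {
  data <- align_model_columns(data, model)
  kmats <- kernel_matrices(data, model$train, model$bandwidths)
  posterior_from_logs(log_component_density(kmats, model$weights),
                      model$lambdas)$posterior
}

#' npEM M-step
#'
#' Mixing proportions as the column means of the posterior matrix.
#'
#' @param posterior N x L posterior matrix.
#' @return Length-L vector of mixing proportions summing to 1.
#' @export
npem_m_step <- function(posterior) {
  colMeans(as.matrix(posterior))
}

#' Fit the non-parametric EM mixture model
#'
#' Starting from hard k-means labels, alternates the mixing-proportion
#' update, the weighted-KDE density update, and the posterior update until
#' either the change in log-likelihood drops below `config$ll_tol` or the
#' maximum absolute change in any posterior entry drops below `config$tol`
#' (or `max_iter` is reached, in which case the model is returned with
#' `converged = FALSE` and a warning). Bandwidths follow
#' [bandwidth_default()] on each pooled scaled column and stay constant
#' across clusters and iterations. All coordinates are treated as
#' conditionally independent given cluster. The fit is deterministic given
#' (data, config).
#'
#' @param data Scaled complete-case matrix (subjects x features).
#' @param config An [npem_config()].
#' @param ref_stats Optional reference statistics (from
#'   [compute_reference_stats()]) stored in the model so external data can
#'   be scaled identically.
#' @return An object of class `npem_model` with elements `L`, `lambdas`,
#'   `weights` (per-cluster KDE weights over training rows), `train`,
#'   `bandwidths`, `support`, `feature_names`, `posterior`, `ref_stats`,
#'   `final_loglik`, `n_iter`, `converged`, `seed`.
#' @export
npem_fit <- function(data, config, ref_stats = NULL) {
  stopifnot(inherits(config, "npem_config"))
  data <- as.matrix(data)
  if (anyNA(data)) stop("npem_fit requires complete-case data")
  n <- nrow(data)
  L <- config$L
  if (is.null(colnames(data))) colnames(data) <- paste0("V", seq_len(ncol(data)))

  bandwidths <- unname(apply(data, 2L, bandwidth_default))
  labels <- npem_init_kmeans(data, L, config$seed)
  post <- matrix(0, n, L)
  post[cbind(seq_len(n), labels)] <- 1

  kmats <- kernel_matrices(data, data, bandwidths)
  converged <- FALSE
  iter <- 0L
  loglik <- NA_real_
  lambdas <- rep(1 / L, L)
  weights <- post
  while (iter < config$max_iter) {
    iter <- iter + 1L
    lambdas <- npem_m_step(post)
    mass <- colSums(post)
    if (any(mass <= 0)) {
      stop("degenerate component: cluster ", which(mass <= 0)[1L],
           " lost all posterior mass at iteration ", iter)
    }
    weights <- sweep(post, 2L, mass, "/")
    es <- posterior_from_logs(log_component_density(kmats, weights), lambdas)
    delta <- max(abs(es$posterior - post))
    post <- es$posterior
    ll_prev <- loglik
    loglik <- es$loglik
    if (delta < config$tol ||
        (!is.na(ll_prev) && abs(loglik - ll_prev) < config$ll_tol)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("npEM did not converge in %d iterations", config$max_iter))
  }
  structure(list(
    L = L,
    lambdas = lambdas,
    weights = weights,
    train = data,
    bandwidths = bandwidths,
    support = unname(t(apply(data, 2L, range))),
    feature_names = colnames(data),
    posterior = post,
    ref_stats = ref_stats,
    final_loglik = loglik,
    n_iter = iter,
    converged = converged,
    seed = config$seed
  ), class = "npem_model")
}

#' @export
print.npem_model <- function(x, ...) {
  cat(sprintf("<npem_model> L = %d, %d training subjects x %d features\n",
              x$L, nrow(x$train), length(x$feature_names)))
  cat("  lambdas:", paste(sprintf("%.3f", x$lambdas), collapse = " "), "\n")
  cat(sprintf("  loglik = %.2f after %d iterations (%s)\n", x$final_loglik,
              x$n_iter, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Retrieve the fitted density for one (feature, cluster) pair
#'
#' @param model A fitted `npem_model`.
#' @param feature Feature name or index.
#' @param cluster Cluster index in 1..L.
#' @return A `wkde` object.
#' @export
npem_density <- function(model, feature, cluster) {
  if (is.character(feature)) feature <- match(feature, model$feature_names)
  if (is.na(feature)) stop("unknown feature")
  stopifnot(cluster >= 1, cluster <= model$L)
  wkde(model$train[, feature], model$weights[, cluster],
       model$bandwidths[feature],
       support = model$support[feature, ])
}

align_model_columns <- function(data, model) {
  data <- as.matrix(data)
  if (!is.null(colnames(data))) {
    if (!setequal(colnames(data), model$feature_names) ||
        anyDuplicated(colnames(data))) {
      stop("data columns do not match model features")
    }
    data <- data[, model$feature_names, drop = FALSE]
  } else if (ncol(data) != length(model$feature_names)) {
    stop("data columns do not match model features")
  }
  data
}

#' Log-likelihood of complete-case data under a fitted npEM model
#'
#' sum_i log sum_k lambda_k prod_j f_jk(x_ij), accumulated in the log
#' domain.
#'
#' @param data Complete-case matrix aligned with the model's features.
#' @param model A fitted `npem_model`.
#' @return The log-likelihood (a scalar).
#' @export
npem_loglik <- function(data, model) {
  data <- align_model_columns(data, model)
  if (anyNA(data)) stop("npem_loglik requires complete-case data")
  kmats <- kernel_matrices(data, model$train, model$bandwidths)
  lp <- sweep(log_component_density(kmats, model$weights), 2L,
              log(model$lambdas), "+")
  sum(row_logsumexp(lp))
}

#' Hard cluster assignments from a fitted model's training posterior
#'
#' @param model A fitted `npem_model`.
#' @return Integer labels in 1..L (argmax posterior per training subject).
#' @export
npem_hard_labels <- function(model) {
  as.integer(max.col(model$posterior, ties.method = "first"))
}
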