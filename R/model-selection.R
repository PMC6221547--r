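#' Bayesian information criterion for an npEM fit
#'
#' BIC = -2 * loglik + nu * ln(N) with nu = L*M + (L - 1): one effective
#' parameter per (cluster, feature) density plus the L - 1 free mixing
#' proportions.
#'
#' @param loglik Maximised log-likelihood.
#' @param L Number of clusters.
#' @param M Number of clustering features.
#' @param N Number of subjects.
#' @return The BIC value (smaller is better).
#' @export
npem_bic <- function(loglik, L, M, N) {
  stopifnot(L >= 1, M >= 1, N >= 1)
  -2 * loglik + npem_nu(L, M) * log(N)
}

#' Effective parameter count nu = L*M + (L - 1)
#'
#' @param L Number of clusters.
#' @param M Number of features.
#' @return Integer nu.
#' @export
npem_nu <- function(L, M) {
  as.integer(L * M + (L - 1))
}

#' Sweep the number of clusters and select by minimum BIC
#'
#' Fits the npEM model for each L in `L_min..L_max` with the same seed and
#' settings, records nu, log-likelihood, BIC and convergence for each, and
#' selects the L with minimum BIC; ties are broken in favour of the smaller
#' L (parsimony). Non-converged fits are flagged in the table, not dropped.
#'
#' @param data Scaled complete-case matrix.
#' @param L_min,L_max Sweep bounds, `1 <= L_min <= L_max <= N`.
#' @param seed Seed passed to each fit.
#' @param max_iter,tol EM settings passed to each fit.
#' @return A list with `table` (data frame: L, nu, loglik, bic, converged,
#'   n_iter) and `selected_L`.
#' @export
npem_sweep_L <- function(data, L_min = 1L, L_max = 20L, seed = 1L,
                         max_iter = 500L, tol = 1e-6) {
  data <- as.matrix(data)
  N <- nrow(data)
  M <- ncol(data)
  stopifnot(L_min >= 1, L_min <= L_max, L_max <= N)
  Ls <- seq.int(L_min, L_max)
  rows <- lapply(Ls, function(L) {
    fit <- withCallingHandlers(
      npem_fit(data, npem_config(L, seed = seed, max_iter = max_iter, tol = tol)),
      warning = function(w) invokeRestart("muffleWarning")
    )
    data.frame(L = L, nu = npem_nu(L, M), loglik = fit$final_loglik,
               bic = npem_bic(fit$final_loglik, L, M, N),
               converged = fit$converged, n_iter = fit$n_iter)
  })
  tab <- do.call(rbind, rows)
  if (any(!tab$converged)) {
    warning("non-converged fits at L = ",
            paste(tab$L[!tab$converged], collapse = ", "))
  }
  # which.min returns the first minimum, i.e. the smallest L on ties
  list(table = tab, selected_L = tab$L[which.min(tab$bic)])
}
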