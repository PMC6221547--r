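# Shared fixtures, built in code at test time.

# Minimal feature metadata for a hand-built table.
tiny_meta <- function(names, domain = "demographic", log_transform = FALSE,
                      lod = NA_real_, is_binary = FALSE) {
  data.frame(
    name = names,
    domain_tag = domain,
    timepoint = "y2",
    log_transform = log_transform,
    lod = lod,
    is_binary = is_binary,
    stringsAsFactors = FALSE
  )
}

tiny_table <- function(values, ids = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(values)))
  cohort_table(values, ids, tiny_meta(colnames(values)))
}

# Three well-separated Gaussian clusters in `m` dimensions; every feature
# carries signal for every cluster contrast (npEM identifiability degrades
# when a contrast lives in a single coordinate).
separated_clusters <- function(n_per = 20L, m = 4L, sep = 6, sd = 0.5,
                               seed = 42L) {
  set.seed(seed)
  centers <- matrix(0, 3L, m)
  centers[2L, ] <- sep * sd
  centers[3L, ] <- -sep * sd
  labels <- rep(1:3, each = n_per)
  x <- centers[labels, ] + matrix(rnorm(3L * n_per * m, sd = sd),
                                  3L * n_per, m)
  colnames(x) <- paste0("f", seq_len(m))
  rownames(x) <- paste0("s", seq_len(nrow(x)))
  list(x = x, labels = labels)
}

# Hand-built two-component model over `m` iid features: cluster 1's density
# is exactly twice cluster 2's at x = 0 for every feature (single kernel at
# 0 vs at h*sqrt(2*log(2))).
two_to_one_model <- function(m = 3L, h = 0.4, lambdas = c(0.5, 0.5)) {
  shift <- h * sqrt(2 * log(2))
  train <- matrix(rep(c(0, shift), each = 1L), nrow = 2L, ncol = m)
  colnames(train) <- paste0("f", seq_len(m))
  structure(list(
    L = 2L,
    lambdas = lambdas,
    weights = diag(2),
    train = train,
    bandwidths = rep(h, m),
    support = matrix(rep(c(-10, 10), each = m), m, 2L),
    feature_names = colnames(train),
    posterior = diag(2),
    ref_stats = NULL,
    final_loglik = NA_real_,
    n_iter = 0L,
    converged = TRUE,
    seed = 1L
  ), class = "npem_model")
}

# Small fitted model on separated synthetic clusters, for classifier tests.
small_fitted_model <- function(seed = 7L) {
  sim <- separated_clusters(n_per = 15L, m = 5L, seed = seed)
  npem_fit(sim$x, npem_config(3L, seed = 1L))
}

# All permutations of 1..n, independent of the package's own helper.
perms_bruteforce <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms_bruteforce(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}
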