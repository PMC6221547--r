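#' Jaccard similarity of two sets
#'
#' |A intersect B| / |A union B|, with the convention that two empty sets
#' have similarity 1.
#'
#' @param a,b Vectors treated as sets (duplicates ignored).
#' @return A value in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1.0)
  length(intersect(a, b)) / u
}

# L_a x L_b matrix of Jaccard similarities between the clusters of two
# labelled partitions over (possibly overlapping) id sets.
jaccard_matrix <- function(ids_a, labels_a, ids_b, labels_b, L_a, L_b) {
  outer(seq_len(L_a), seq_len(L_b), Vectorize(function(i, j) {
    jaccard_index(ids_a[labels_a == i], ids_b[labels_b == j])
  }))
}

# All permutations of 1..n (n small).
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub), n - 1L))
  }))
}

#' Align cluster labels of a partition to a reference partition
#'
#' Finds the one-to-one assignment of the partition's clusters to the
#' reference clusters that maximises the total Jaccard similarity over the
#' L x L Jaccard matrix (exhaustive over permutations for L <= 7, greedy
#' beyond; greedy is also used when the cluster counts differ, with
#' unmatched clusters reported).
#'
#' @param ids,labels Subject ids and integer cluster labels of the
#'   partition to relabel.
#' @param ref_ids,ref_labels The reference partition.
#' @return A list with `perm` (element k is the reference cluster matched
#'   to partition cluster k, `NA` if unmatched), `relabeled` (labels mapped
#'   into reference space) and `jaccard` (the L x L similarity matrix).
#' @export
align_labels <- function(ids, labels, ref_ids, ref_labels) {
  L_a <- max(labels)
  L_b <- max(ref_labels)
  jm <- jaccard_matrix(ids, labels, ref_ids, ref_labels, L_a, L_b)
  if (L_a == L_b && L_a <= 7L) {
    perms <- permutations(L_a)
    scores <- apply(perms, 1L, function(p) sum(jm[cbind(seq_len(L_a), p)]))
    perm <- as.integer(perms[which.max(scores), ])
  } else {
    perm <- rep(NA_integer_, L_a)
    jm_work <- jm
    for (step in seq_len(min(L_a, L_b))) {
      best <- arrayInd(which.max(jm_work), dim(jm_work))
      perm[best[1L]] <- best[2L]
      jm_work[best[1L], ] <- -Inf
      jm_work[, best[2L]] <- -Inf
    }
    if (anyNA(perm)) {
      warning("differing cluster counts: unmatched clusters ",
              paste(which(is.na(perm)), collapse = ", "))
    }
  }
  list(perm = perm, relabeled = perm[labels], jaccard = jm)
}

# Refit on `data`, align to the reference partition and return per-cluster
# Jaccard similarities against the reference, restricted to `ids`.
refit_jaccard <- function(data, config, ref_ids, ref_labels) {
  fit <- withCallingHandlers(
    npem_fit(data, config),
    warning = function(w) invokeRestart("muffleWarning")
  )
  labels <- npem_hard_labels(fit)
  ids <- rownames(data)
  keep_ref <- ref_ids %in% ids
  al <- align_labels(ids, labels, ref_ids[keep_ref], ref_labels[keep_ref])
  L <- length(ref_labels_levels <- seq_len(max(ref_labels)))
  jac <- vapply(ref_labels_levels, function(k) {
    jaccard_index(ids[al$relabeled == k & !is.na(al$relabeled)],
                  ref_ids[keep_ref][ref_labels[keep_ref] == k])
  }, numeric(1))
  list(jaccard = jac, converged = fit$converged)
}

loo_stability <- function(data, config, seeds, leave_out, subsample_every) {
  data <- as.matrix(data)
  if (is.null(rownames(data))) rownames(data) <- paste0("S", seq_len(nrow(data)))
  if (leave_out == "individual" && nrow(data) <= config$L + 1L) {
    stop("too few subjects to refit after leaving one out")
  }
  if (leave_out == "feature" && ncol(data) < 2L) {
    stop("cannot leave out the only feature")
  }
  ref_fit <- withCallingHandlers(
    npem_fit(data, config),
    warning = function(w) invokeRestart("muffleWarning")
  )
  ref_labels <- npem_hard_labels(ref_fit)
  ref_ids <- rownames(data)
  L <- config$L

  n_entities <- if (leave_out == "individual") nrow(data) else ncol(data)
  idx <- seq(1L, n_entities, by = subsample_every)

  per_iter <- list()
  n_nonconv <- 0L
  for (seed in seeds) {
    for (i in idx) {
      if (leave_out == "individual") {
        sub <- data[-i, , drop = FALSE]
      } else {
        sub <- data[, -i, drop = FALSE]
      }
      cfg <- npem_config(L, seed = seed, max_iter = config$max_iter,
                         tol = config$tol)
      res <- refit_jaccard(sub, cfg, ref_ids, ref_labels)
      if (!res$converged) n_nonconv <- n_nonconv + 1L
      per_iter[[length(per_iter) + 1L]] <- data.frame(
        seed = seed, left_out = i, cluster = seq_len(L),
        jaccard = res$jaccard, converged = res$converged
      )
    }
  }
  long <- do.call(rbind, per_iter)
  per_cluster <- vapply(seq_len(L), function(k) {
    mean(long$jaccard[long$cluster == k])
  }, numeric(1))
  structure(list(
    per_cluster_jaccard = per_cluster,
    long = long,
    seeds = seeds,
    leave_out = leave_out,
    subsample_every = subsample_every,
    n_refits = length(seeds) * length(idx),
    n_nonconverged = n_nonconv
  ), class = "stability_report")
}

#' Leave-one-individual-out cluster stability
#'
#' Refits the npEM model on each (N-1) x M subset (optionally every q-th
#' individual only), aligns the refit partition to the reference partition
#' via [align_labels()], computes per-cluster Jaccard similarities with the
#' left-out subject excluded from both sides, and averages over all refits
#' and seeds. Non-converged refits are flagged and kept.
#'
#' @param data Scaled complete-case matrix with subject rownames.
#' @param config An [npem_config()]; its seed fits the reference partition.
#' @param seeds Integer seeds for the refit initializations (default 1:10).
#' @param subsample_every Refit only for every q-th left-out entity
#'   (default 1 = full leave-one-out); logged in the report.
#' @return A `stability_report`: per-cluster mean Jaccard, the long table
#'   (seed, left_out, cluster, jaccard, converged), seeds, refit counts.
#' @export
loo_individual_stability <- function(data, config, seeds = 1:10,
                                     subsample_every = 1L) {
  loo_stability(data, config, seeds, "individual", subsample_every)
}

#' Leave-one-feature-out cluster stability
#'
#' As [loo_individual_stability()], but refitting on each N x (M-1) subset
#' with one clustering feature removed at a time.
#'
#' @inheritParams loo_individual_stability
#' @return A `stability_report`.
#' @export
loo_feature_stability <- function(data, config, seeds = 1:10,
                                  subsample_every = 1L) {
  loo_stability(data, config, seeds, "feature", subsample_every)
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> leave-one-%s-out, %d refits (%d seeds%s)\n",
              x$leave_out, x$n_refits, length(x$seeds),
              if (x$subsample_every > 1L)
                sprintf(", every %d-th entity", x$subsample_every) else ""))
  cat("  per-cluster mean Jaccard:",
      paste(sprintf("%.3f", x$per_cluster_jaccard), collapse = " "), "\n")
  if (x$n_nonconverged > 0L) {
    cat("  non-converged refits:", x$n_nonconverged, "\n")
  }
  invisible(x)
}

#' Silhouette widths for a clustered, scaled matrix
#'
#' Per-subject silhouette widths s(i) = (b(i) - a(i)) / max(a(i), b(i))
#' with Euclidean distance on the scaled features, where a(i) is the mean
#' within-cluster distance and b(i) the mean distance to the nearest other
#' cluster; members of singleton clusters get width 0 by convention.
#'
#' @param data Scaled complete-case matrix.
#' @param labels Integer cluster labels, at least two distinct values.
#' @return A list with `widths` (per subject), `per_cluster` (mean width by
#'   cluster) and `overall` (grand mean).
#' @export
silhouette_widths <- function(data, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("silhouette widths require at least two clusters")
  }
  sil <- cluster::silhouette(labels, dist(as.matrix(data)))
  widths <- sil[, "sil_width"]
  per_cluster <- tapply(widths, labels, mean)
  list(widths = as.numeric(widths),
       per_cluster = as.numeric(per_cluster),
       overall = mean(widths))
}
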