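test_that("Jaccard index has the set-overlap semantics", {
  expect_equal(jaccard_index(1:5, 1:5), 1.0)
  expect_equal(jaccard_index(1:3, 4:6), 0.0)
  expect_equal(jaccard_index(1:3, 2:4), 0.5)
  expect_equal(jaccard_index(integer(0), integer(0)), 1.0)
  # symmetry and the equals-one-iff-equal property on random sets
  set.seed(40)
  for (i in 1:20) {
    a <- sample(20, sample(10, 1))
    b <- sample(20, sample(10, 1))
    expect_equal(jaccard_index(a, b), jaccard_index(b, a))
    j <- jaccard_index(a, b)
    expect_true(j >= 0 && j <= 1)
    if (j == 1) expect_setequal(a, b)
  }
})

test_that("label alignment maximises total Jaccard over all permutations", {
  ids <- 1:10
  ref <- rep(1:2, each = 5)
  # identical partitions: identity permutation
  al <- align_labels(ids, ref, ids, ref)
  expect_equal(al$perm, 1:2)
  # swapped labels: the swap permutation
  al2 <- align_labels(ids, 3L - ref, ids, ref)
  expect_equal(al2$perm, 2:1)
  expect_equal(al2$relabeled, ref)
  # worked example: {A=1..8, B=9,10} vs {R1=1..7,9; R2=8,10}
  part <- c(rep(1L, 8), 2L, 2L)
  refp <- c(rep(1L, 7), 2L, 1L, 2L)
  al3 <- align_labels(ids, part, ids, refp)
  expect_equal(al3$perm, c(1L, 2L))

  # optimality by exhaustive enumeration for random partitions, L <= 4
  set.seed(41)
  for (L in 2:4) {
    for (rep in 1:10) {
      labs <- sample(L, 30, replace = TRUE)
      refl <- sample(L, 30, replace = TRUE)
      labs[1:L] <- 1:L; refl[1:L] <- 1:L  # ensure all labels present
      al <- align_labels(1:30, labs, 1:30, refl)
      score <- sum(al$jaccard[cbind(1:L, al$perm)])
      best <- max(vapply(perms_bruteforce(L), function(p) {
        sum(al$jaccard[cbind(1:L, p)])
      }, numeric(1)))
      expect_equal(score, best)
    }
  }
})

test_that("leave-one-individual-out stability is high for separated clusters", {
  sim <- separated_clusters(n_per = 12L, m = 4L, seed = 42L)
  rep_ind <- loo_individual_stability(sim$x, npem_config(3L, seed = 1L),
                                      seeds = 1:2, subsample_every = 4L)
  expect_true(all(rep_ind$per_cluster_jaccard >= 0.95))
  expect_true(all(rep_ind$per_cluster_jaccard <= 1))
  expect_equal(rep_ind$n_refits, 2L * length(seq(1, 36, by = 4)))
  # long table covers every (seed, left-out, cluster) combination
  expect_equal(nrow(rep_ind$long), rep_ind$n_refits * 3L)
  expect_error(
    loo_individual_stability(sim$x[1:3, ], npem_config(3L, seed = 1L),
                             seeds = 1L),
    "too few")
})

test_that("leave-one-feature-out degrades the cluster its feature defines", {
  # f1 separates clusters 1 vs {2,3}; only f2 splits cluster 3 from 2
  set.seed(43)
  n_per <- 15L
  labels <- rep(1:3, each = n_per)
  f1 <- c(-4, 4, 4)[labels] + rnorm(3 * n_per, sd = 0.4)
  f2 <- c(0, 0, 6)[labels] + rnorm(3 * n_per, sd = 0.4)
  x <- cbind(f1 = f1, f2 = f2)
  rownames(x) <- paste0("s", seq_len(nrow(x)))
  rep_feat <- loo_feature_stability(x, npem_config(3L, seed = 1L), seeds = 1L)
  long <- rep_feat$long
  c3_without_f2 <- long$jaccard[long$left_out == 2L & long$cluster == 3L]
  c3_without_f1 <- long$jaccard[long$left_out == 1L & long$cluster == 3L]
  expect_lt(c3_without_f2, 0.6)   # cluster 3 collapses without its feature
  expect_gt(c3_without_f1, 0.9)   # but survives losing the other
  expect_error(loo_feature_stability(x[, 1, drop = FALSE],
                                     npem_config(2L, seed = 1L), seeds = 1L),
               "only feature")
})

test_that("unperturbed refits give Jaccard exactly one", {
  sim <- separated_clusters(n_per = 12L, m = 4L, seed = 44L)
  rep_feat <- loo_feature_stability(sim$x, npem_config(3L, seed = 1L),
                                    seeds = 1L, subsample_every = 2L)
  # all features equally informative and clusters far apart: near-perfect
  expect_true(all(rep_feat$per_cluster_jaccard >= 0.95))
})

test_that("silhouette widths behave per the Rousseeuw definition", {
  # two tight, far-apart clusters: widths near one
  set.seed(45)
  x <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
             matrix(rnorm(40, 10, 0.1), 20, 2))
  labels <- rep(1:2, each = 20)
  sil <- silhouette_widths(x, labels)
  expect_true(all(sil$widths > 0.9))
  expect_true(all(sil$widths >= -1 & sil$widths <= 1))
  # invariance to global translation
  sil_shift <- silhouette_widths(x + 100, labels)
  expect_equal(sil$widths, sil_shift$widths, tolerance = 1e-12)

  # hand-computed widths on a 1-D toy, via the (b - a)/max(a, b) formula
  xt <- matrix(c(0, 1, 10, 11), ncol = 1)
  lt <- c(1, 1, 2, 2)
  silt <- silhouette_widths(xt, lt)
  a1 <- 1; b1 <- mean(c(10, 11))
  expect_equal(silt$widths[1], (b1 - a1) / max(a1, b1))

  # singleton cluster member gets width zero by convention
  xs <- matrix(c(0, 0.5, 9), ncol = 1)
  sils <- silhouette_widths(xs, c(1, 1, 2))
  expect_equal(sils$widths[3], 0)

  expect_error(silhouette_widths(x, rep(1, 40)), "two clusters")
})

test_that("stability and silhouette rise with cluster separation", {
  seps <- c(1.5, 3, 6)
  jac <- sil <- numeric(3)
  for (i in seq_along(seps)) {
    sim <- separated_clusters(n_per = 12L, m = 4L, sep = seps[i], seed = 46L)
    fit <- npem_fit(sim$x, npem_config(3L, seed = 1L))
    st <- loo_individual_stability(sim$x, npem_config(3L, seed = 1L),
                                   seeds = 1L, subsample_every = 9L)
    jac[i] <- mean(st$per_cluster_jaccard)
    sil[i] <- silhouette_widths(sim$x, npem_hard_labels(fit))$overall
  }
  expect_true(all(diff(jac) >= 0))
  expect_true(all(diff(sil) >= 0))
})
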