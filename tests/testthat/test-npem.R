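test_that("k-means initialization is deterministic and separates clear clouds", {
  sim <- separated_clusters(n_per = 15L, m = 3L, seed = 10L)
  l1 <- npem_init_kmeans(sim$x, 3L, seed = 5L)
  l2 <- npem_init_kmeans(sim$x, 3L, seed = 5L)
  expect_identical(l1, l2)
  expect_true(all(tabulate(l1, 3L) > 0L))
  # perfectly separable two-cloud case
  x2 <- rbind(matrix(-1, 10, 2), matrix(1, 10, 2)) +
    matrix(rnorm(40, sd = 0.05), 20, 2)
  lab <- npem_init_kmeans(x2, 2L, seed = 1L)
  expect_equal(length(unique(lab[1:10])), 1L)
  expect_equal(length(unique(lab[11:20])), 1L)
  expect_false(lab[1] == lab[11])
  # L = 1 trivially labels everything 1
  expect_identical(npem_init_kmeans(x2, 1L, seed = 1L), rep(1L, 20L))
})

test_that("M-step returns posterior column means", {
  post <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(npem_m_step(post), c(0.5, 0.5))
  expect_equal(npem_m_step(matrix(1 / 3, 5, 3)), rep(1 / 3, 3))
})

test_that("KDE estimation weights each cluster by its normalised posterior column", {
  set.seed(12)
  x <- matrix(rnorm(20), 10, 2)
  labels <- rep(1:2, each = 5)
  post <- matrix(0, 10, 2)
  post[cbind(1:10, labels)] <- 1
  dens <- npem_estimate_kdes(x, post, bandwidths = c(0.3, 0.3))
  # hard posterior: cluster 1's KDE puts equal weight on members, none elsewhere
  k11 <- dens[[1]][[1]]
  expect_equal(k11$w[1:5], rep(0.2, 5))
  expect_equal(k11$w[6:10], rep(0, 5))
  # equal-weight hard KDE matches a plain KDE over the members
  ref <- wkde(x[1:5, 1], h = 0.3)
  at <- seq(-2, 2, 0.5)
  expect_equal(wkde_eval(k11, at), wkde_eval(ref, at))
  expect_error(npem_estimate_kdes(x, cbind(rep(1, 10), rep(0, 10)),
                                  c(0.3, 0.3)), "degenerate")
})

test_that("E-step posterior follows the product-of-densities formula", {
  # density ratio 2 per feature over 3 features -> posterior (8/9, 1/9)
  model <- two_to_one_model(m = 3L)
  post <- npem_posterior(model, rep(0, 3))
  expect_equal(as.numeric(post), c(8 / 9, 1 / 9), tolerance = 1e-12)

  # identical densities across clusters -> posterior equals lambda
  model_eq <- two_to_one_model(m = 3L, lambdas = c(0.3, 0.7))
  model_eq$train[, ] <- 0
  post_eq <- npem_posterior(model_eq, rep(0.2, 3))
  expect_equal(as.numeric(post_eq), c(0.3, 0.7), tolerance = 1e-12)

  # one-hot lambda forces the posterior regardless of densities
  model_hot <- two_to_one_model(m = 3L, lambdas = c(1, 0))
  expect_equal(as.numeric(npem_posterior(model_hot, rep(0, 3))), c(1, 0))
})

test_that("posterior rows sum to one across iterations and inputs", {
  sim <- separated_clusters(n_per = 12L, m = 4L, seed = 13L)
  fit <- npem_fit(sim$x, npem_config(3L, seed = 2L))
  expect_equal(rowSums(fit$posterior), rep(1, nrow(sim$x)), tolerance = 1e-9)
  expect_equal(sum(fit$lambdas), 1, tolerance = 1e-9)
  expect_true(all(fit$lambdas >= 0))
  post <- npem_e_step(sim$x, fit)
  expect_equal(rowSums(post), rep(1, nrow(sim$x)), tolerance = 1e-9)
})

test_that("fit recovers a well-separated 1-D two-component mixture", {
  set.seed(14)
  n <- 200L
  labels <- rep(1:2, each = n / 2)
  x <- matrix(rnorm(n, mean = c(-2, 2)[labels], sd = 0.3), ncol = 1)
  colnames(x) <- "f1"
  fit <- npem_fit(x, npem_config(2L, seed = 1L))
  expect_true(fit$converged)
  expect_equal(sort(fit$lambdas), c(0.5, 0.5), tolerance = 0.05)
  hard <- npem_hard_labels(fit)
  agreement <- max(mean(hard == labels), mean(hard == 3L - labels))
  expect_gte(agreement, 0.99)
})

test_that("fit with L = 1 degenerates to a single weighted KDE", {
  set.seed(15)
  x <- matrix(rnorm(30), ncol = 2)
  fit <- npem_fit(x, npem_config(1L, seed = 1L))
  expect_equal(fit$lambdas, 1)
  expect_equal(as.numeric(fit$posterior), rep(1, 15))
  expect_equal(fit$weights[, 1], rep(1 / 15, 15))
})

test_that("fit is deterministic given data and config", {
  sim <- separated_clusters(n_per = 10L, m = 3L, seed = 16L)
  f1 <- npem_fit(sim$x, npem_config(3L, seed = 4L))
  f2 <- npem_fit(sim$x, npem_config(3L, seed = 4L))
  expect_identical(f1$lambdas, f2$lambdas)
  expect_identical(f1$posterior, f2$posterior)
  expect_identical(npem_hard_labels(f1), npem_hard_labels(f2))
})

test_that("log-likelihood matches a brute-force direct-product evaluation", {
  set.seed(17)
  x <- matrix(rnorm(15), 5, 3)
  colnames(x) <- paste0("f", 1:3)
  fit <- npem_fit(x, npem_config(2L, seed = 1L))
  # brute force: plain products, no log-domain tricks
  brute <- 0
  for (i in 1:5) {
    total <- 0
    for (k in 1:2) {
      prod_jk <- fit$lambdas[k]
      for (j in 1:3) {
        kde <- npem_density(fit, j, k)
        prod_jk <- prod_jk * wkde_eval(kde, x[i, j])
      }
      total <- total + prod_jk
    }
    brute <- brute + log(total)
  }
  expect_equal(npem_loglik(x, fit), brute, tolerance = 1e-10)
  expect_equal(fit$final_loglik, brute, tolerance = 1e-10)
  # permutation invariance over rows
  expect_equal(npem_loglik(x[5:1, ], fit), brute, tolerance = 1e-10)
  expect_error(npem_loglik(x[, c(1, 1, 2)], fit), "match")
})

test_that("npEM posteriors track the analytic Bayes posteriors of the true model", {
  set.seed(18)
  n <- 2000L
  labels <- 1L + (runif(n) < 0.5)
  mu <- c(-2, 2)[labels]
  x <- matrix(rnorm(n, mu, 1), ncol = 1)
  colnames(x) <- "f1"
  fit <- npem_fit(x, npem_config(2L, seed = 1L))
  bayes1 <- 0.5 * dnorm(x[, 1], -2, 1) /
    (0.5 * dnorm(x[, 1], -2, 1) + 0.5 * dnorm(x[, 1], 2, 1))
  # align component order before comparing (component means are sum(x * w_k))
  ord <- order(vapply(1:2, function(k) {
    sum(fit$train[, 1] * fit$weights[, k])
  }, numeric(1)))
  fitted1 <- fit$posterior[, ord[1]]
  expect_lt(mean(abs(fitted1 - bayes1)), 0.05)
})
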