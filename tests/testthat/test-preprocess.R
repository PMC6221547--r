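test_that("feature filtering removes strictly-above-threshold features only", {
  # 10 subjects x 4 features: 25%, exactly 20%, 30%, 0% missing
  v <- matrix(rnorm(40), 10, 4)
  v[1:2, 1] <- NA           # 20% -> retained (boundary)
  v[1:3, 2] <- NA           # 30% -> removed
  v[1:2, 3] <- NA; v[5, 3] <- NA  # 30% -> removed
  tab <- tiny_table(v)
  out <- suppressMessages(filter_features(tab, 0.20))
  expect_identical(out$feature_meta$name, c("f1", "f4"))

  # brute-force count on a larger random mask
  set.seed(3)
  v2 <- matrix(rnorm(500), 50, 10)
  v2[sample(length(v2), 120)] <- NA
  tab2 <- tiny_table(v2)
  out2 <- suppressMessages(filter_features(tab2, 0.20))
  keep_expected <- colSums(is.na(v2)) / 50 <= 0.20
  expect_identical(out2$feature_meta$name, tab2$feature_meta$name[keep_expected])

  v3 <- matrix(NA_real_, 5, 3)
  expect_error(filter_features(tiny_table(v3), 0.2), "unusable")
})

test_that("subject filtering removes strictly-above-threshold subjects", {
  set.seed(4)
  v <- matrix(rnorm(100 * 10), 100, 10)
  heavy <- sample(100, 12)
  for (i in heavy) v[i, sample(10, 4)] <- NA  # 40% missing
  tab <- tiny_table(v)
  out <- suppressMessages(filter_subjects(tab, 0.30))
  expect_equal(nrow(out$values), 88)
  expect_setdiff <- setdiff(tab$subject_ids[heavy], out$subject_ids)
  expect_length(expect_setdiff, 12)

  # exactly 30% missing is retained
  v2 <- matrix(rnorm(30), 3, 10)
  v2[1, 1:3] <- NA
  out2 <- filter_subjects(tiny_table(v2), 0.30)
  expect_equal(nrow(out2$values), 3)
})

test_that("complete/low-missingness split is exhaustive and disjoint", {
  set.seed(5)
  v <- matrix(rnorm(220 * 6), 220, 6)
  with_any <- sample(220, 30)
  for (i in with_any) v[i, sample(6, 1)] <- NA
  parts <- split_complete_low_missing(tiny_table(v))
  expect_equal(nrow(parts$complete_case$values), 190)
  expect_equal(nrow(parts$low_missingness$values), 30)
  expect_false(anyNA(parts$complete_case$values))
  expect_true(all(rowSums(is.na(parts$low_missingness$values)) > 0))
  expect_length(
    intersect(parts$complete_case$subject_ids,
              parts$low_missingness$subject_ids), 0)

  expect_error(split_complete_low_missing(
    tiny_table(matrix(c(NA, 1, 2, NA), 2, 2))), "complete-case")
})

test_that("filters on a fully observed table are the identity", {
  v <- matrix(rnorm(60), 10, 6)
  tab <- tiny_table(v)
  out <- filter_subjects(filter_features(tab, 0.2), 0.3)
  expect_identical(out$values, tab$values)
})

test_that("half-LOD substitution follows the assay rules and is idempotent", {
  expect_equal(substitute_lod(0.02, lod = 0.03), 0.015)    # IgE kU/L
  expect_equal(substitute_lod(0.0001, lod = 0.0003), 0.00015)  # IgG4 ug/L
  expect_equal(substitute_lod(0.1, lod = 0.4), 0.2)        # IgG mg/L
  expect_equal(substitute_lod(0.03, lod = 0.03), 0.03)     # at LOD: unchanged
  v <- c(0.01, NA, 0.5, 0.029)
  once <- substitute_lod(v, 0.03)
  expect_identical(substitute_lod(once, 0.03), once)
  expect_true(is.na(once[2]))
  expect_error(substitute_lod(v, -1), "positive")
})

test_that("non-positive cytokine responses are floored", {
  expect_equal(substitute_nonpositive(-0.5, 0.01), 0.01)      # protein pg/ml
  expect_equal(substitute_nonpositive(0, 0.000001), 0.000001) # mRNA units
  expect_equal(substitute_nonpositive(3.2, 0.01), 3.2)
  expect_error(substitute_nonpositive(1, 0), "positive")
})

test_that("log10 transform preserves missing and rejects non-positives", {
  expect_equal(log10_transform(c(1, 100, NA)), c(0, 2, NA))
  expect_equal(log10_transform(0.015), -1.8239, tolerance = 1e-4)
  expect_error(log10_transform(c(1, 0), feature = "ige_01"), "ige_01")
})

test_that("reference stats use midpoint medians and reject zero ranges", {
  m <- cbind(a = c(0, 1, 2), b = c(1, 2, 3))
  rs <- compute_reference_stats(m)
  expect_equal(rs$median, c(1, 2))
  expect_equal(rs$min, c(0, 1))
  expect_equal(rs$max, c(2, 3))
  rs4 <- compute_reference_stats(cbind(x = c(1, 2, 3, 10)))
  expect_equal(rs4$median, 2.5)
  expect_error(compute_reference_stats(cbind(k = c(5, 5, 5))), "zero-range")
  expect_error(compute_reference_stats(cbind(k = c(1, NA, 3))), "complete-case")
})

test_that("positional scaling maps complete-case data into [-1,1] with median 0", {
  set.seed(6)
  m <- matrix(rnorm(200, sd = 5), 40, 5)
  colnames(m) <- paste0("f", 1:5)
  rs <- compute_reference_stats(m)
  sc <- positional_scale(m, rs)
  expect_true(all(sc >= -1 & sc <= 1))
  expect_equal(unname(apply(sc, 2, median)), rep(0, 5), tolerance = 1e-12)
  # round trip
  expect_equal(positional_unscale(sc, rs), m, tolerance = 1e-12,
               ignore_attr = TRUE)
  # worked example: feature {0,1,2}, x = 2 -> 0.5
  rs3 <- compute_reference_stats(cbind(f = c(0, 1, 2)))
  expect_equal(as.numeric(positional_scale(cbind(f = 2), rs3)), 0.5)
  # external value below training min may leave [-1,1]
  expect_equal(as.numeric(positional_scale(cbind(f = -3), rs3)), -2)
  # misaligned columns rejected
  expect_error(positional_scale(cbind(g = 1), rs3), "align")
})

test_that("preprocess_cohort runs the full chain on a synthetic cohort", {
  co <- generate_cohort(cas_like_config(), seed = 11)
  prep <- suppressMessages(preprocess_cohort(co$table))
  expect_false(anyNA(prep$complete_case))
  expect_true(all(prep$complete_case >= -1 & prep$complete_case <= 1))
  meds <- apply(prep$complete_case, 2, median)
  expect_equal(max(abs(meds)), 0, tolerance = 1e-12)
  # excluded outcome feature and heavy-missingness features are gone
  expect_false("wheeze_age5" %in% colnames(prep$complete_case))
  expect_false(any(grepl("^dropout_", colnames(prep$complete_case))))
  # antibody columns are finite after LOD rule + log10
  ab <- prep$filtered$feature_meta$domain_tag == "antibody"
  expect_true(all(is.finite(prep$complete_case_table$values[, ab])))
  # low-missingness rows all have some missingness, under the threshold
  lm_na <- rowMeans(is.na(prep$low_missingness))
  if (length(lm_na)) expect_true(all(lm_na > 0 & lm_na <= 0.30))
})
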