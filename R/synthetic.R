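#' Configuration for the synthetic cohort generator
#'
#' Describes a latent three-cluster (by default) birth cohort with the
#' statistical structure the analysis assumes: a log-normal antibody block
#' left-censored at assay LODs, a Poisson infection-count block, a binary
#' and count demographic block, missingness at both the feature and the
#' subject level, and a cluster-dependent binary outcome (an age-5-wheeze
#' analogue). Cluster separation is controlled by a single scalar
#' multiplier on the per-cluster location offsets so that recovery tests
#' can sweep it.
#'
#' @param n_subjects Number of subjects (default 220).
#' @param mixing Cluster mixing proportions, summing to 1
#'   (default `c(0.41, 0.49, 0.10)`).
#' @param outcome_probs Per-cluster outcome probabilities
#'   (default `c(0.25, 0.21, 0.76)`).
#' @param separation Scalar multiplier on the antibody-block per-cluster
#'   log-mean offsets, in units of the within-cluster log10 SD (default 1,
#'   i.e. offsets of 1-3 within-cluster SDs per feature).
#' @param n_antibody,n_infection,n_binary,n_count Features per block
#'   (defaults 36/12/8/4, a reduced roster of 60 clustering features).
#' @param antibody_sigma Within-cluster SD of antibody levels on the log10
#'   scale (default 0.5).
#' @param n_dropout_features Extra antibody features generated with heavy
#'   missingness, destined for removal by the feature filter (default 3).
#' @param dropout_feature_missing Missing fraction of those features
#'   (default 0.30).
#' @param frac_heavy_subjects Fraction of subjects in the high-missingness
#'   stratum removed by the subject filter (default 0.10), with per-cell
#'   missing probability `heavy_missing` (default 0.45).
#' @param frac_lowmiss_subjects Fraction in the limited-missingness stratum
#'   that survives filtering but is not complete-case (default 0.15), with
#'   per-cell missing probability `lowmiss_missing` (default 0.08).
#' @param heavy_missing,lowmiss_missing Per-cell missing probabilities of
#'   the two strata.
#' @param seed Default generation seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 220L,
                             mixing = c(0.41, 0.49, 0.10),
                             outcome_probs = c(0.25, 0.21, 0.76),
                             separation = 1,
                             n_antibody = 36L,
                             n_infection = 12L,
                             n_binary = 8L,
                             n_count = 4L,
                             antibody_sigma = 0.5,
                             n_dropout_features = 3L,
                             dropout_feature_missing = 0.30,
                             frac_heavy_subjects = 0.10,
                             heavy_missing = 0.45,
                             frac_lowmiss_subjects = 0.15,
                             lowmiss_missing = 0.08,
                             seed = 1L) {
  if (abs(sum(mixing) - 1) > 1e-8) stop("mixing proportions must sum to 1")
  if (length(outcome_probs) != length(mixing)) {
    stop("one outcome probability per cluster required")
  }
  if (any(outcome_probs < 0 | outcome_probs > 1)) {
    stop("outcome probabilities must lie in [0, 1]")
  }
  if (separation < 0) stop("separation must be non-negative")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Default configuration emulating the discovery cohort
#'
#' N = 220 subjects, 60 clustering features, three clusters with mixing
#' proportions (0.41, 0.49, 0.10) and outcome probabilities
#' (0.25, 0.21, 0.76) — the cluster-size and age-5-wheeze structure of a
#' high-risk birth cohort with a small extreme-phenotype cluster.
#'
#' @return A `synthetic_config`.
#' @export
cas_like_config <- function() synthetic_config()

# Deterministic per-feature cluster-offset signatures, in units of the
# within-cluster SD: cluster 3 is the extreme phenotype on every antibody
# class; IgG separates cluster 1 from 2 in the opposite direction.
antibody_signatures <- list(
  ige  = c(0, 1, 3),
  igg4 = c(0, 2, 3),
  igg  = c(1, 0, 2)
)
antibody_bases <- c(ige = -1, igg4 = -3, igg = 0.3)     # log10 native units
antibody_lods <- c(ige = 0.03, igg4 = 0.0003, igg = 0.4) # kU/L, ug/L, mg/L

infection_rate_mult <- list(c(1, 0.7, 1.8), c(0.7, 1, 2.2))
infection_base_rates <- c(1.4, 1.0, 2.0, 0.6)

binary_probs <- list(c(0.25, 0.45, 0.70), c(0.50, 0.30, 0.60),
                     c(0.35, 0.55, 0.40), c(0.40, 0.40, 0.65))
count_rates <- list(c(2, 1.5, 2.5), c(1, 1, 1.8))

#' Generate a synthetic cohort with known cluster labels and outcomes
#'
#' Draws cluster labels from the mixing proportions; antibody features as
#' log-normals with cluster-shifted log10 means (values below the assay
#' LOD are kept as drawn, so preprocessing exercises the half-LOD rule);
#' infection features as cluster-rate Poisson counts; demographic features
#' as Bernoulli indicators and Poisson counts; missingness completely at
#' random per cell within a limited-missingness stratum, a heavier stratum
#' destined for subject filtering, and a few heavily missing features
#' destined for feature filtering; and a binary outcome per subject from
#' its cluster's outcome probability. The outcome is also carried in the
#' table as an `exclude`-flagged clinical feature so the preprocessing
#' roster rules are exercised. Reproducible: the same config and seed give
#' an identical cohort.
#'
#' @param config A [synthetic_config()].
#' @param seed Generation seed (default `config$seed`).
#' @return A list of class `synthetic_cohort`: `table` (a
#'   [cohort_table()]), `true_labels`, `outcomes`, `config`.
#' @export
generate_cohort <- function(config = cas_like_config(), seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(seed, {
    n <- config$n_subjects
    K <- length(config$mixing)
    labels <- sample.int(K, n, replace = TRUE, prob = config$mixing)
    outcomes <- stats::rbinom(n, 1L, config$outcome_probs[labels])

    cols <- list()
    meta <- list()
    add_feature <- function(values, name, domain, log_transform = FALSE,
                            lod = NA_real_, is_binary = FALSE,
                            exclude = FALSE, timepoint = "y2") {
      cols[[name]] <<- values
      meta[[name]] <<- data.frame(
        name = name, domain_tag = domain, timepoint = timepoint,
        log_transform = log_transform, lod = lod, is_binary = is_binary,
        exclude = exclude, stringsAsFactors = FALSE
      )
    }

    iso_names <- names(antibody_signatures)
    for (f in seq_len(config$n_antibody)) {
      iso <- iso_names[((f - 1L) %% 3L) + 1L]
      sig <- antibody_signatures[[iso]]
      mu <- antibody_bases[[iso]] +
        config$separation * config$antibody_sigma * sig[labels]
      vals <- 10^stats::rnorm(n, mu, config$antibody_sigma)
      add_feature(vals, sprintf("%s_%02d", iso, f), "antibody",
                  log_transform = TRUE, lod = antibody_lods[[iso]])
    }

    for (f in seq_len(config$n_infection)) {
      mult <- infection_rate_mult[[((f - 1L) %% 2L) + 1L]]
      base <- infection_base_rates[((f - 1L) %% 4L) + 1L]
      add_feature(stats::rpois(n, base * mult[labels]),
                  sprintf("lri_%02d", f), "infection")
    }

    for (f in seq_len(config$n_binary)) {
      p <- binary_probs[[((f - 1L) %% 4L) + 1L]]
      add_feature(stats::rbinom(n, 1L, p[labels]),
                  sprintf("demo_bin_%02d", f), "demographic",
                  is_binary = TRUE, timepoint = "birth")
    }

    for (f in seq_len(config$n_count)) {
      r <- count_rates[[((f - 1L) %% 2L) + 1L]]
      add_feature(stats::rpois(n, r[labels]),
                  sprintf("demo_cnt_%02d", f), "demographic",
                  timepoint = "birth")
    }

    # heavily missing antibody features, removed by the feature filter
    for (f in seq_len(config$n_dropout_features)) {
      vals <- 10^stats::rnorm(n, antibody_bases[["ige"]], config$antibody_sigma)
      vals[stats::runif(n) < config$dropout_feature_missing] <- NA
      add_feature(vals, sprintf("dropout_%02d", f), "antibody",
                  log_transform = TRUE, lod = antibody_lods[["ige"]])
    }

    # outcome carried as an exclude-flagged clinical feature
    add_feature(outcomes, "wheeze_age5", "clinical", is_binary = TRUE,
                exclude = TRUE, timepoint = "y5")

    values <- do.call(cbind, cols)
    rownames(values) <- sprintf("subj_%03d", seq_len(n))

    # subject-level missingness strata over the clustering roster
    n_heavy <- round(config$frac_heavy_subjects * n)
    n_lowmiss <- round(config$frac_lowmiss_subjects * n)
    strata <- sample(rep(c("heavy", "lowmiss", "complete"),
                         c(n_heavy, n_lowmiss, n - n_heavy - n_lowmiss)))
    roster <- !vapply(meta, function(m) m$exclude, logical(1)) &
      !grepl("^dropout_", names(cols))
    for (i in which(strata == "heavy")) {
      drop <- stats::runif(sum(roster)) < config$heavy_missing
      values[i, which(roster)[drop]] <- NA
    }
    for (i in which(strata == "lowmiss")) {
      drop <- stats::runif(sum(roster)) < config$lowmiss_missing
      values[i, which(roster)[drop]] <- NA
    }

    table <- cohort_table(values, rownames(values),
                          do.call(rbind, unname(meta)))
    structure(list(table = table, true_labels = labels, outcomes = outcomes,
                   strata = strata, config = config, seed = seed),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d features, %d clusters (seed %d)\n",
              nrow(x$table$values), ncol(x$table$values),
              length(x$config$mixing), x$seed))
  cat("  true cluster sizes:", paste(tabulate(x$true_labels), collapse = "/"), "\n")
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (cohort, metadata, truth, config).
#' @export
write_synthetic_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    cohort = file.path(dir, "cohort.csv"),
    meta = file.path(dir, "feature_meta.csv"),
    truth = file.path(dir, "truth.csv"),
    config = file.path(dir, "config.json")
  )
  write_cohort_csv(cohort$table, paths$cohort, paths$meta)
  utils::write.csv(
    data.frame(subject_id = cohort$table$subject_ids,
               true_label = cohort$true_labels,
               outcome = cohort$outcomes),
    paths$truth, row.names = FALSE
  )
  jsonlite::write_json(unclass(cohort$config), paths$config,
                       digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
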