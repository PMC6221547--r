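# npemcohort

Unsupervised discovery of latent trajectory phenotypes in birth-cohort
data. `npemcohort` is aimed at epidemiologists and biostatisticians who
have a subjects × features table of mixed early-life measurements —
antibody titres (IgE, IgG, IgG4), respiratory-infection counts,
demographic and clinical background — and want to identify latent
subgroups, assign new or partially measured subjects to them, and know how
much to trust the result.

## The model

Subjects are draws from a finite mixture with `L` components. Conditional
on component `k`, the `M` features are independent, each with its own
*nonparametric* density: the fit consists of mixing proportions λ_k and,
for every (feature j, cluster k), a weighted kernel density estimate

    f_jk(u) = Σ_i w_ik · φ((u − x_ij)/h_j) / h_j

with standard normal kernel φ, per-feature constant bandwidth
h_j = 0.9·min(sd, IQR/1.34)·n^(−1/5), and weights w_ik given by the
posterior membership probabilities. The non-parametric EM (npEM)
algorithm alternates the posterior (E) step, the mixing-proportion (M)
step and the kernel-density step from a seed-controlled k-means
initialization, stopping on log-likelihood stabilisation. The number of
clusters is chosen by minimum BIC, `−2·log p̂ + ν·log N` with
`ν = L·M + (L−1)`.

Classification of subjects with arbitrary missing features uses the
density-product posterior

    P(k | x_i) = λ_k Π_j f_jk(x_ij) / Σ_l λ_l Π_j f_jl(x_ij)

with a density of exactly 1 for missing features (the feature drops out of
the product) and clipping of out-of-range values to the training support;
subjects are assigned only when the maximum posterior strictly exceeds a
threshold (default 0.90). Cluster stability is assessed by
leave-one-individual-out and leave-one-feature-out refits scored with
per-cluster Jaccard indices over multiple seeds, and internal validity by
silhouette widths.

Around the model sit a preprocessing module (missingness filters at
>20% per feature / >30% per subject, half-LOD substitution for
left-censored immunoassays, cytokine floors, log10 transform, and
median/range "positional standardisation" scaling) and a synthetic cohort
generator with known cluster labels and outcomes that drives all
end-to-end tests.

## Worked example

```r
library(npemcohort)

cohort <- generate_cohort(cas_like_config(), seed = 1)
#> <synthetic_cohort> 220 subjects, 64 features, 3 clusters (seed 1)
#>   true cluster sizes: 97/104/19

prep <- preprocess_cohort(cohort$table)
#> filter_features: removed 3 of 63 features (> 20% missing)
#> filter_subjects: removed 22 of 220 subjects (> 30% missing)

sweep <- npem_sweep_L(prep$complete_case, 1, 6, seed = 1)
sweep$selected_L
#> [1] 3

fit <- npem_fit(prep$complete_case, npem_config(3, seed = 1),
                ref_stats = prep$ref_stats)
fit
#> <npem_model> L = 3, 165 training subjects x 60 features
#>   lambdas: 0.079 0.479 0.442
#>   loglik = 4354.22 after 1 iterations (converged)

cls <- npem_classify(fit, prep$low_missingness, threshold = 0.90)
table(cls$label, useNA = "ifany")
#>  1  2  3
#>  5 16 12

stab <- loo_individual_stability(prep$complete_case, npem_config(3, seed = 1),
                                 seeds = 1:3, subsample_every = 12)
stab$per_cluster_jaccard
#> [1] 1 1 1
```

Reading: preprocessing removed the three heavily missing features and 22
heavily missing subjects, splitting the rest into 165 complete-case
subjects (which train the mixture) and 33 low-missingness subjects. The
BIC sweep picks three clusters — the generating number — and the fitted
mixing proportions (0.079, 0.479, 0.442) recover the cluster shares
present in the training subset. All 33 partially observed subjects clear
the 0.90 posterior threshold, and the leave-one-out Jaccard indices of 1
say the partition is unchanged by dropping any sampled individual at this
separation. The whole chain is also available as a single call,
`run_pipeline()`, or from the shell via `inst/scripts/run_pipeline.R`.

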