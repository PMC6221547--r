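---
title: "Non-parametric EM mixture clustering for birth-cohort phenotyping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{npem-methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npemcohort)
```

## The problem

Early-childhood wheeze and asthma are heterogeneous: children with similar
symptoms can follow very different trajectories of allergic sensitisation,
respiratory infection and eventual disease. One way to study this
heterogeneity is to cluster subjects of a birth cohort on a broad roster of
early-life measurements — antibody titres (IgE, IgG, IgG4 against specific
allergens), infection counts (lower/upper respiratory infections per year),
and demographic or clinical background — and then ask how the resulting
latent groups differ in later outcomes such as wheeze at age 5.

Such rosters mix continuous, count and binary features, most of them far
from Gaussian, with missingness at both the feature and the subject level.
`npemcohort` implements an analysis built for exactly this setting:

1. **Preprocessing**: quality-control filters, limit-of-detection handling,
   log transformation, and a range-based scaling that puts every feature on
   a comparable scale.
2. **npEM mixture model**: a non-parametric EM algorithm in which each
   (feature, cluster) pair carries a weighted kernel density estimate
   rather than a parametric density.
3. **BIC model selection** for the number of clusters.
4. **Density-product classification** of subjects with arbitrary missing
   features, including subjects of external cohorts that share only part
   of the feature roster.
5. **Stability and validity assessment** via leave-one-out Jaccard indices
   and silhouette widths.
6. A **synthetic cohort generator** that emulates the data structure and
   provides ground truth for end-to-end testing.

## Preprocessing

Features missing in more than 20% of subjects are removed, then subjects
missing more than 30% of the remaining features; both thresholds are
strict (a feature missing in exactly 20% of subjects is kept). The
filtered table splits into a *complete-case* subset (no missing values;
used to fit the mixture) and a *low-missingness* complement (classified
afterwards through the fitted densities). Missing values are never
imputed; the classifier handles them explicitly.

Assay-specific substitutions precede the log transform:

* antibody readings below the instrument's limit of detection (LOD) are
  replaced by half the LOD — e.g. IgE below 0.03 kU/L becomes 0.015 kU/L,
  IgG4 below 0.0003 µg/L becomes 0.00015 µg/L, IgG below 0.4 mg/L becomes
  0.2 mg/L;
* stimulated-minus-control cytokine responses that are zero or negative
  (control ≥ stimulated) are floored at 0.01 pg/ml (protein) or 0.000001
  units (mRNA).

Skewed features are then log10-transformed, and every feature is scaled by
*positional standardisation*:

$$x_{ij} \mapsto \frac{x_{ij} - \mathrm{med}(x_j)}{\max(x_j) - \min(x_j)}$$

with median, maximum and minimum computed once on the complete-case subset
and stored. On the training data every scaled value lies in $[-1, 1]$ with
column median 0; external data scaled with the *same stored statistics*
may fall outside $[-1, 1]$ and is handled by density clipping (below).
Binary features pass through the same formula, becoming two-point
features — accepted, so that every feature contributes on an equal
footing. Even-length medians are midpoints of the central order
statistics. Zero-range (constant) features are dropped with a message:
they carry no information and make the scaling undefined.

## The npEM mixture model

Subjects are modelled as draws from a finite mixture with $L$ components.
Conditional on component $k$, the $M$ coordinates are independent, each
with its own unknown density $f_{jk}$ — no parametric family is assumed.
The fitted object consists of mixing proportions $\lambda_k$ and, for each
(feature $j$, cluster $k$), a weighted kernel density estimate

$$f_{jk}(u) = \sum_i w_{ik}\, \frac{1}{h_j}\,\varphi\!\left(\frac{u - x_{ij}}{h_j}\right),$$

where $\varphi$ is the standard normal density and the weights $w_{ik}$
are the $k$-th posterior column normalised to sum to one.

The algorithm iterates:

* **E-step** — posterior membership probabilities
  $p_{ik} \propto \lambda_k \prod_j f_{jk}(x_{ij})$, computed as sums of
  log densities to avoid underflow over a hundred-plus features;
* **M-step** — $\lambda_k$ as posterior column means;
* **density step** — refresh every $f_{jk}$ with the new posterior
  weights.

**Initialization.** Hard labels from seeded k-means
(`stats::kmeans`, 10 restarts, best within-SS). A single random start can
land in a poor local optimum when one cluster is small (a tenth of the
cohort); ten restarts make recovery of such clusters reliable while
keeping the initialization fully determined by (data, L, seed). On an
empty-cluster failure the centroids are redrawn from the same seeded
stream a bounded number of times.

**Bandwidths.** One constant bandwidth per feature,
$h_j = 0.9\,\min(\mathrm{sd}, \mathrm{IQR}/1.34)\,n^{-1/5}$, computed on
the pooled scaled complete-case column and held fixed across clusters and
iterations (falling back to $0.9\,\mathrm{sd}\,n^{-1/5}$ when ties
collapse the IQR, floored at $10^{-6}$). Pooled constant bandwidths
slightly oversmooth individual components, which in return damps the
overfitting that per-component adaptive bandwidths would invite.

**Convergence.** Iteration stops when the absolute change in
log-likelihood falls below `ll_tol` ($10^{-8}$) or the maximum absolute
change in any posterior entry falls below `tol` ($10^{-6}$), whichever
comes first, with `max_iter` = 500 as a guarded ceiling. The
log-likelihood criterion is the primary one, and it is not merely a
convention: with a single coordinate the npEM mixture density telescopes
to the pooled KDE,
$\sum_k \lambda_k f_k(u) = \tfrac1N \sum_i K_h(u - x_i)$, for *any*
posterior, so the likelihood surface is exactly flat and a
posterior-change criterion lets the components drift from a good
initialization toward the uninformative fixed point where every posterior
row equals $\lambda$. The likelihood stop halts at the initialized
solution instead. With many informative coordinates the two criteria
agree. The log-likelihood is monitored, not asserted monotone — npEM has
no guaranteed ascent property. Per-row products of densities are floored
at $10^{-300}$ before logs so a single extreme value cannot produce
$-\infty$.

This also delimits what the model can and cannot identify: mixtures of
conditionally independent nonparametric coordinates are identifiable with
three or more informative coordinates, but a cluster contrast carried by
a single feature behaves like the 1-D case and can dissolve. The
leave-one-feature-out stability analysis is the diagnostic for exactly
that situation.

## Choosing the number of clusters

For each $L$ in a sweep (default 1–6 at desk scale; the interface accepts
any range) the model is fitted with the same seed and scored by

$$\mathrm{BIC} = -2\log\hat p + \nu \log N, \qquad \nu = L M + (L - 1),$$

counting one effective parameter per (cluster, feature) density plus the
free mixing proportions; natural log, the standard convention. Minimum
BIC wins; ties break toward the smaller $L$ for parsimony. Non-converged
fits are flagged in the sweep table rather than dropped.

## Classifying subjects with missing features

For a new subject the posterior is
$P(k \mid x) \propto \lambda_k \prod_{j} f_{jk}(x_j)$ over the observed
features only, with two rules:

* a missing feature contributes density exactly 1 (equivalently, the
  feature drops out of the product — identical to classifying through a
  model from which that feature was removed, a property the test suite
  checks to $10^{-12}$);
* a value outside the feature's training support is assigned the density
  of the nearer support endpoint, making the posterior constant in each
  tail. The support is the observed training range: with a Gaussian
  kernel every point has positive density, so the data range is the
  meaningful notion of "where the density was estimated".

A subject is assigned to its argmax cluster only when the maximum
posterior strictly exceeds the threshold (default 0.90); otherwise it is
left unclassified. For cross-cohort use, `restrict_model()` subsets a
fitted model to the features an external cohort shares; external data are
scaled with the *training* model's reference statistics, not their own —
the densities are otherwise not comparable. `concordance()` measures
agreement between two classifications of the same subjects.

## Stability and validity

Leave-one-individual-out: the model is refitted on each $(N-1) \times M$
subset (optionally every $q$-th subject, with $q$ recorded), the refit
partition is aligned to the reference partition, and per-cluster Jaccard
similarities are computed with the left-out subject excluded from both
sides; results are averaged over refits and seeds (default seeds 1–10).
Leave-one-feature-out proceeds analogously on $N \times (M-1)$ subsets.
Alignment assigns refit clusters to reference clusters one-to-one so as
to maximise total Jaccard similarity (exhaustive over permutations for
$L \le 7$, greedy beyond; matching a cluster to its *least* similar
counterpart would make the index meaningless). Silhouette widths follow
the classical $(b - a)/\max(a, b)$ definition with Euclidean distance on
the scaled features, singletons scored 0 (`cluster::silhouette` supplies
the computation).

Full leave-one-out at cohort scale ($N \approx 186$, $M \approx 174$,
10 seeds) is thousands of refits; the `subsample_every` argument trades
coverage for time and is always recorded in the report.

## The synthetic cohort generator

`cas_like_config()` emulates the structure of a high-risk birth cohort:
220 subjects, three latent clusters with mixing proportions
(0.41, 0.49, 0.10), and a binary age-5-wheeze-like outcome with
per-cluster probabilities (0.25, 0.21, 0.76) — a small extreme-risk
cluster beside two large low-risk ones. Features come in blocks:

* 36 antibody features, log-normal with cluster-shifted log10 means
  (within-cluster SD 0.5) and left-censored at realistic LODs (0.03 kU/L,
  0.0003 µg/L, 0.4 mg/L for IgE-, IgG4- and IgG-like features), so the
  half-LOD rule is genuinely exercised;
* 12 infection-count features, Poisson with cluster-specific rates around
  1–2 events per year, the extreme cluster highest;
* 8 binary and 4 count demographic features with moderate cluster
  contrasts.

Cluster separation is one scalar (`separation`, default 1, i.e. antibody
log-mean offsets of 1–3 within-cluster SDs per feature) so monotonicity
checks can sweep it; the default is chosen to be comfortably identifiable
rather than near a phase boundary, since the package's correctness tests,
not its power against hard cases, are the point. Missingness is MCAR in
three strata: 10% of subjects draw ~45% missing cells (removed by the
subject filter), 15% draw ~8% (the low-missingness classification path),
the rest are complete; three extra antibody features carry 30%
missingness and are removed by the feature filter. The outcome is also
carried in the table as an `exclude`-flagged clinical feature to exercise
the roster rules — outcome variables never enter the clustering.

What the generator does *not* emulate: longitudinal correlation between
repeated measurements of the same assay, missingness that depends on the
data (MNAR), block correlation within allergen panels, and the full
174-feature roster (60 features keep leave-one-out testing at desk
scale). Passing tests therefore demonstrate correctness of the machinery
and recoverability under the stated conditions, not performance on any
real cohort.

## Worked example

```{r example, eval = FALSE}
library(npemcohort)

cohort <- generate_cohort(cas_like_config(), seed = 1)
prep <- preprocess_cohort(cohort$table)

sweep <- npem_sweep_L(prep$complete_case, 1, 6, seed = 1)
sweep$selected_L                      # 3

fit <- npem_fit(prep$complete_case, npem_config(sweep$selected_L, seed = 1),
                ref_stats = prep$ref_stats)
fit$lambdas

cls <- npem_classify(fit, prep$low_missingness, threshold = 0.90)
table(cls$label, useNA = "ifany")

stab <- loo_individual_stability(prep$complete_case,
                                 npem_config(3, seed = 1),
                                 seeds = 1:3, subsample_every = 12)
stab$per_cluster_jaccard
```

The same path, end to end, is wrapped by `run_pipeline()` and by the
script `inst/scripts/run_pipeline.R`.

## Problem sizes and runtime choices

The package's own test and acceptance runs use the synthetic default
(220 subjects, ~60 clustering features), BIC sweeps over $L = 1..6$, and
subsampled leave-one-out (every 12th subject, 3 seeds); at these sizes
the full pipeline completes in seconds on a single core. All of these are
arguments, not constants — cohort-scale runs (full sweep to $L = 20$,
complete leave-one-out over 10 seeds) use the same code paths.

## Known limitations

* npEM identifiability requires the cluster structure to be spread over
  several coordinates; single-feature contrasts can dissolve (see the
  convergence discussion above).
* Silhouette widths on broad, heterogeneous rosters are expected to be
  small even for meaningful clusters: distance in the full scaled feature
  space is dominated by features irrelevant to cluster membership.
* The conditional-independence assumption ignores correlation between
  related assays (e.g. IgE titres against different allergens); the
  posterior products are then overconfident to a degree the stability
  analysis only partially reveals.
* Classification of external cohorts assumes the training densities
  transfer; the package deliberately refuses to refit or rescale on
  external data, and feature matching quality is the user's
  responsibility.
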