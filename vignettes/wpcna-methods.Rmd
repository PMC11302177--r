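---
title: "Models and methods behind wpcna"
author: "wpcna authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wpcna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`wpcna` implements a complete systems-level analysis chain for multi-batch
isobaric-label (TMT) brain proteomics: batch correction against pooled
global-internal-standard (GIS) channels, bootstrap covariate regression with
a protected diagnosis term, signed weighted co-expression network
construction with a mean-denominator topological overlap matrix (TOM),
module characterisation (eigenproteins, kME, hubs, trait correlation,
gene-set enrichment), cross-cohort module preservation, and a
betweenness-centrality bottleneck analysis on TOM subgraphs. A seeded
synthetic cohort generator with planted ground truth makes every stage
testable without any external download. This vignette documents the models,
the tunable parameters, the numerical choices, and the limits of what the
synthetic validation can show.

# The synthetic cohort generator

`simulateCohort()` draws log2 abundances under an additive latent-factor
model. For protein $i$ in module $M$ and biological sample $s$ of diagnosis
group $g$:

$$x_{is} = \mu_i + \lambda_i m_{M,s} + a_{age}\,age_s + a_{sex}\,sex_s +
a_{pmi}\,pmi_s + \delta_{i,b(s)} + \varepsilon_{is}$$

with module scores $m_{M,s} = \Delta_{M,g} + \eta$, $\eta \sim N(0,1)$,
residual noise $\varepsilon \sim N(0, \sigma^2)$ and per-(protein, batch)
offsets $\delta \sim N(0, \sigma_b^2)$. Key default choices, fixed once as
the package's study conditions:

* **Cohort design**: 47/33/47/11 CTL/PD/PDD/DLB biological samples across
  10 batches of 16 channels, one channel per batch reserved for the GIS
  (the protein-wise mean of that batch's biological samples plus
  $N(0, \sigma/4)$ noise). 1,000 proteins: 8 modules of 200–40 members,
  144 unassigned background proteins, and one bottleneck protein.
* **Loadings** $\lambda_i \sim U(0.4, 1)$. The wide range gives each module
  a hub gradient — strongly and weakly connected members — which is a
  defining feature of real co-expression modules (module membership kME in
  brain networks spans roughly 0.4–0.95). Near-uniform loadings produce
  "flat" modules whose intramodular connectivity carries no reproducible
  pattern, which distorts connectivity-based preservation statistics.
* **Noise** $\sigma = 0.6$ log2 units, tuned so the median within-module
  pairwise correlation is about 0.6 at the default loadings.
* **Batch SD** 0.5 log2 units, applied per (protein, batch). A batch term
  constant across proteins would be removed by any per-sample centring;
  protein-specific batch shifts are what TMT batch effects look like and
  what GIS-referenced median polish exists to remove.
* **Group effects** are latent-unit severity curves (e.g. module M1:
  0 / 0.3 / 0.8 / 1.0 for CTL / PD / PDD / DLB); labels are mapped to the
  curve by severity so a two-group CTL/DLB design receives the full-range
  contrast. The first group is always the reference (effect 0).
* **Covariates**: age slope 0.02 log2/yr, sex offset 0.2, PMI slope 0.01
  log2/h, identical across proteins. Age $\sim N(75, 8^2)$ truncated to
  [55, 95], sex Bernoulli(0.5), PMI $\sim N(12, 6^2)$ truncated at 1 h;
  the ground truth lives in the slopes, not these distributions.
* **Pathology traits** (CERAD 0–3, Braak 0–6, frontal LB score 0–3) are
  monotone rank discretisations of weighted module scores (quartile,
  septile and quartile bins; ties broken by sample order). No extra trait
  noise is added: discretisation is the noise.
* **Missingness** is completely at random at rate 0.15, below the 0.5
  presence filter so planted proteins survive filtering by default. The
  missingness mechanism of real TMT data is unknown to us; an
  intensity-dependent mechanism is deliberately not the default.
* **The bottleneck protein** loads with weight 2.0 on the three
  disease-concordant modules (M1, M2, M5) and belongs to none of them
  (planted membership "bottleneck"). With three *independent* targets the
  achievable kME per target is capped at $1/\sqrt{3} \approx 0.577$; using
  concordant modules, whose latent scores correlate through the shared
  diagnosis shifts, lifts the population kME per target to ~0.58–0.63 —
  the moderate, clearly-below-hub band that motivates a bottleneck
  analysis in the first place. Sampling noise at 138 samples is about
  ±0.06 around that value.

`simulateReplication()` freezes memberships, loadings and bottleneck
weights and redraws everything sample-side — the situation of an
independent cohort measuring the same biology. Group effects can be
overridden (e.g. sign-flipped) and selected modules can be scrambled into
pure noise to model non-replicating biology. `simulateMarkerSets()` emits
GMT collections with a controlled overlap fraction per planted module plus
uniform decoys.

**What the generator does not emulate**: peptide/PSM-level quantification,
ratio compression, isotopic interference, intensity-dependent missingness,
correlated covariates (age–diagnosis confounding), or nested module
structure. Passing tests therefore demonstrate algorithmic correctness and
calibration under a clean additive model, not robustness to every artefact
of real TMT data.

# Preprocessing

**Missingness filter.** A protein observed in fewer than 50% of samples is
removed; nothing is imputed, and all downstream statistics use
pairwise-complete observations.

**TAMPOR batch correction** (`tampor()`) alternates two median centrings
until the largest cell change falls below `tol`: per protein and batch,
subtract the median of that batch's GIS channels; per sample, subtract the
sample median over proteins. Stopping rules are `tol = 1e-8` on the maximum
absolute change and 250 iterations (the algorithm's description leaves
these open; convergence on our cohorts takes ~50 iterations). When a
protein has no observed GIS value in a batch, the intra-batch median
stands in. The output is a twice-centred log2 ratio matrix; within-batch
sample contrasts survive up to per-sample offsets.

A caveat worth stating plainly: the per-sample median factor subtracts a
mixture of whatever signal is common across many proteins. On the default
synthetic cohort, 85% of proteins carry planted module signal, so the
sample medians track a combination of the module scores and the corrected
matrix carries a small shared distortion — enough to cap
eigenprotein-vs-planted-score correlations around 0.86–0.92 even for a
perfect network. Real cohorts quantify thousands of proteins of which a
small fraction move with disease, so the median is far more stable there.
For this reason the *network recovery* validation runs on cohorts
generated without batch effects and preprocessed without TAMPOR (filter,
regression, outlier removal only), so that its stated premise —
within-module r ≈ 0.6 entering the network step — actually holds; TAMPOR
is validated separately on batch-variance collapse and idempotence, where
its behaviour is unambiguous.

**Bootstrap covariate regression** (`regressCovariates()`) fits, per
protein, 1000 weighted least-squares models on stratified bootstrap
resamples (multinomial case weights per protected level, so every
diagnosis level stays represented) of abundance on [diagnosis dummies +
age + sex + PMI], takes the per-covariate median coefficient, and
subtracts $\sum_c \hat\beta_c (x_c - \bar x_c)$. Mean-centring the
covariates preserves the grand mean and cannot change any downstream
correlation. Diagnosis coefficients are estimated (protecting the disease
contrast from absorption by correlated covariates) but never subtracted.
Proteins with fewer complete observations than parameters + 2, or observed
in fewer than two diagnosis levels, are left unregressed and flagged.

One property of latent-factor data is worth knowing when interpreting the
validation: members of one module share their latent score's sampling
error, so their covariate coefficient errors are correlated and do not
average out within a module. Slope recovery is therefore pinned on
background proteins (independent errors), and diagnosis-contrast
preservation is measured as the pooled regression slope of post- on
pre-correction contrasts across all planted proteins.

**Connectivity outliers** (`removeConnectivityOutliers()`): each sample's
summed pairwise correlation to all other samples (over standardised
protein profiles) is Z-scored; samples beyond |Z| > 3 are removed in a
single pass. Iterating the removal is deliberately not done.

# The signed network

The robust correlation is the biweight midcorrelation,
$u_i = (x_i - \mathrm{med}\,x) / (9\,\mathrm{MAD}\,x)$, weights
$(1-u^2)^2$ zeroed beyond $|u| \ge 1$, with medians and MADs per variable
from all observed values and sums over pairwise-complete entries.
Variables with zero MAD fall back to Pearson weighting and are flagged.
P-values use the Student-t transform on the pairwise-complete count.

Adjacency is the signed map $a_{ij} = ((1+r_{ij})/2)^\beta$ with
$\beta = 11$ by default (12 and 7.5 are the conventional settings for
stiffer and looser cohorts; `pickSoftThreshold()` reports scale-free fit
diagnostics but the build always uses the configured power). The TOM is

$$TOM_{ij} = \frac{\ell_{ij} + a_{ij}}{f(k_i, k_j) + 1 - a_{ij}},\qquad
\ell_{ij} = \sum_{u \ne i,j} a_{iu}a_{uj},$$

with $f$ the mean of the two connectivities (the "min" variant is also
implemented). The mean denominator damps the overlap inflation between a
weakly and a strongly connected protein.

**Dynamic dendrogram cut.** Average-linkage clustering on $1 - TOM$ is
followed by a hybrid cut written for this package. The static cut height
defaults to 99% of the way from the 5th percentile to the maximum of the
joining heights. Within each static branch, two phases run:

1. *Glue splitting*: a branch whose mean pairwise member dissimilarity
   exceeds the deep-split scatter threshold (deepSplit 0–4 maps to
   0.95/0.91/0.82/0.73/0.64 of the tree's height range above its minimum;
   smaller thresholds split deeper) is background "glue" and is split into
   its children recursively. Fragments that never reach coherence fall
   below the minimum module size (default 25) and dissolve to unassigned.
2. *Mixture probing*: a scatter-coherent branch can still be two tight
   modules bridged by chained background spurs, so it is descended past
   sub-minimum spurs to the first node with two large children; when the
   joining height exceeds both children's internal scatter by the
   deep-split minimum gap, the branch is split and each child probed
   again. Otherwise the branch is one cluster and is kept whole. The gap
   criterion is what keeps a homogeneous module from being shredded: for
   random internal splits the joining height approximately equals the
   child scatter.

A PAM-style stage then assigns each unassigned protein to the nearest
module medoid (by $1-TOM$), restricted to medoids within the protein's own
static branch when `pam_respect_dendro` (the default), and only when the
protein lies within the module's own radius. A plain fixed-height cut
(`method = "static"`) exists as a debugging fallback. Equivalence with the
reference hybrid cut implementation is asserted behaviourally — planted
partitions are recovered with adjusted Rand index above 0.9 on the default
cohort — not line-by-line.

**Eigenproteins** are first right singular vectors of the standardised
member submatrix, with residual missing cells imputed at the protein mean
(zero after standardisation; a sample with no observed member values gets
a missing entry), signs aligned so members correlate positively on
average. **kME** is the signed bicor of each protein against each
eigenprotein. **Merging** clusters eigenproteins on $1 - cor$ and
collapses groups below the 0.07 cut height (eigenprotein correlation above
0.93), iterating to a fixed point; taking merge groups from a dendrogram
cut rather than pairwise sweeps makes the result order-independent.
**Clean-up** iterates (up to 30 rounds, re-enforcing the minimum size and
recomputing eigenproteins each round): a protein moves to a foreign module
whose kME beats its own with p below 0.05, and a protein whose own-module
kME is non-significant becomes unassigned. Modules are finally renumbered
by decreasing size (M1 largest) with the conventional colour aliases;
grey/unassigned is reserved.

# Module characterisation

Module–trait relationships are bicor (or Pearson) correlations of
eigenproteins against numeric traits and 0/1 diagnosis indicators, with
stars at 0.05/0.01/0.001. Hubs are the top 20% of each module by
own-module kME; kME ties break by whole-network connectivity and then
protein id, so outputs are deterministic. Gene-set enrichment is the
one-tailed Fisher exact test (equivalently the hypergeometric upper tail)
of each GMT set against each module over the network background, with
sample odds ratios, Benjamini–Hochberg q across the grid (`p.adjust`), and
the one-sided normal z transform of p capped at 38. Protein ids collapse
to the symbol before the "|" separator, uppercased, before matching.

The risk-gene surrogate consumes precomputed per-gene association
p-values, filters at p < 0.05, and runs the same Fisher machinery; a
SNP-level gene association model is out of scope. Significance is called
at z ≥ 1.28 to match a reporting convention in this literature; note that
1.28 is the one-sided 10% normal quantile, so the conventional equation of
z = 1.28 with "p = 0.05" should be read as a convention, not an identity —
the package reproduces the threshold without endorsing the mapping.

# Cross-cohort preservation

`modulePreservation()` reduces the classical 20-statistic permutation
composite to four documented statistics over the shared protein universe:
density (mean intramodular adjacency in the test cohort; proportion of
member variance explained by the test eigenprotein) and connectivity
(correlation of intramodular connectivity vectors ref-vs-test; correlation
of intramodular correlation entries ref-vs-test). The null permutes module
labels — size-matched random member sets — `n_perm` times (seeded;
below 50 warns). Component Zs are medians within each family,
$Z_{summary}$ is the mean of the two composites, and a component whose
null is (near-)degenerate (sd below $10^{-8}$, e.g. the connectivity
correlations in a self-comparison, where observed and permuted values are
identically 1) is flagged missing and dropped from the composite.
Categories are inclusive: $Z \ge 1.96$ preserved, $Z \ge 10$ highly
preserved.

A behaviour specific to shared-truth cohort pairs deserves note: random
member sets mix proteins from several modules, and that block pattern
itself replicates across cohorts, so the label-permutation null for the
connectivity correlations is high. A destroyed module can therefore score
*below* the null (Z around −2 to −3) rather than at zero, and the
connectivity composite is conservative for real modules. Density
statistics separate planted from random modules unambiguously, and the
validation asserts preservation calls at the category level, which is also
the level at which the reduction to four statistics can honestly claim
equivalence with the reference composite.

`syntheticEigenproteins()` assembles, in a test cohort, the top 20% of
each reference module's members by kME, computes their eigenprotein under
the same SVD and sign rules, tests it across test-cohort diagnosis groups
by one-way ANOVA, and reports the direction of each group's shift against
the reference group. `moduleOverlap()` cross-tabulates two partitions and
reports hypergeometric overlap p-values with BH correction.

# Bottleneck analysis

The procedure is fixed as: extract the complete TOM-weighted subgraph on
the union of the chosen modules' members (proteins outside those modules
are excluded even if topologically adjacent); remove edges strictly below
the mean edge weight (ties at the mean survive); compute
source/target-restricted betweenness with the source module's members as
sources and the remaining members as targets; rank the source module's
proteins by g descending (ties by own-module kME, then id). Thresholding
before subgraph extraction is *not* equivalent and is not offered.

Betweenness uses Brandes-style dependency accumulation with the target set
restricting which endpoints contribute. Shortest paths are hop-count by
default: the procedure removes sub-mean edges precisely to binarise
"strong co-expression", and nothing in the source description suggests
weighted paths; a `tom_distance` mode (lengths $1 - TOM$) is provided for
sensitivity analysis. Scores are normalised by the number of valid
(source, target) pairs by default; both the path mode and the
normalisation are configurable because the original convention is not
printed, and the defaults are recorded in every result object. With
sources = targets = all nodes the function reproduces classical
(ordered-pair) betweenness, which is how it is cross-checked against
exhaustive path enumeration.

# Validation design and problem sizes

The package's own validation (the testthat suite and
`scripts/acceptance.R`) runs entirely on generated cohorts, sized so the
full suite completes in a few minutes: the default 1,000-protein,
138-sample cohort for network recovery and preservation; a 301-protein,
80-sample cohort for regression; a 300-protein, 4-batch, deliberately
signal-light cohort (most proteins unassigned, noise 0.5) for batch
correction, so the planted batch fraction of variance (>20% before
correction) is not diluted by planted biology; 50 replicates of a
320-protein, 138-sample cohort for the bottleneck ranking; and 100 random
matrices/graphs against brute-force oracles for the TOM and betweenness
implementations. Batch-explained variance is measured as the mean adjusted
R² of per-protein fits on batch (the unadjusted R² of a 4-level factor on
~50 samples is biased upward by ~6 points under the null, which would mask
the collapse the correction achieves).

# Known limitations

* Single-block network construction only; cohorts beyond ~20k proteins
  would need a block-wise approximation that is deliberately out of scope.
* The hybrid cut is behaviourally, not numerically, equivalent to the
  reference implementation; on dendrograms with heavily nested real-data
  structure the two may differ more than on planted blocks.
* The preservation composite uses 4 statistics, not 20; agreement with the
  full composite is claimed at the preservation-category level only.
* MCAR missingness and independent covariates are idealisations; the
  bootstrap regression has not been validated under covariate–diagnosis
  confounding.
* The z ≥ 1.28 risk-gene convention and the unadjusted p < 0.05 volcano
  threshold mirror reporting conventions rather than recommended practice;
  FDR columns are always emitted alongside.
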