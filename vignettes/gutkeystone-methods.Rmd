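---
title: "Keystone taxa and cross-cohort microbiome association analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Keystone taxa and cross-cohort microbiome association analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutkeystone)
```

## The analysis this package implements

`gutkeystone` packages a complete cross-cohort gut-microbiome epidemiology
workflow built around a natural-experiment exposure. The motivating design
is the 1959–1961 Chinese famine: adults sampled decades later are classified
by birth year into exposure windows, and the group born in 1959 — exposed in
utero and through the first two postnatal years, the "first 1000 days of
life" — is contrasted against the no-exposed control group born 1962–1964.
The scientific chain has three links:

1. **Exposure → community.** Alpha diversity (observed richness, Shannon,
   Pielou, Faith's phylogenetic diversity) and community structure
   (Bray–Curtis principal coordinates, PERMANOVA) are compared between
   exposure groups within each cohort, with covariate adjustment.
2. **Community → keystone taxa.** Co-abundance networks are inferred per
   cohort by three estimators (Pearson on CLR data, SparCC, and
   neighborhood-selection sparse inverse covariance), keystone taxa are the
   nodes whose eigenvector centrality exceeds the empirical 95% quantile of
   their network, and a per-sample *keystone taxa index* sums the
   CLR-transformed abundances of the keystones shared by all cohorts.
3. **Keystones → disease.** The index (per SD) enters covariate-adjusted
   linear models against exposure groups and logistic models against type 2
   diabetes; per-cohort estimates are pooled by DerSimonian–Laird
   random-effects meta-analysis.

Because the real cohort data are access-controlled, the package ships a
synthetic multi-cohort generator with planted effects, and every stage is
validated against it plus hand-computable oracles.

## Compositional preprocessing

Counts are filtered at the study's stated values: samples need depth
≥ 5000 reads, a known birth year, and no recent antibiotic use; genera
detected in fewer than 10% of a cohort's samples are dropped before network
inference (the boundary prevalence of exactly 10% is retained). Two zero
strategies deliberately coexist, mirroring the two analysis paths:

* the **Pearson network path** replaces zeros multiplicatively
  (`multiplicative_impute()`): each zero becomes 0.65 × the sample's
  smallest nonzero relative abundance and the nonzero parts are rescaled so
  the composition still closes to 1, preserving their ratios; the result is
  CLR-transformed;
* the **keystone index path** adds a pseudo-count of 1 to raw counts before
  the CLR.

The 0.65 multiplier is the common convention for multiplicative replacement;
it only matters through the log of the imputed part and results are
insensitive to it in the 0.5–0.8 range.

## Diversity and community structure

Diversity indices run by default on the sample-filtered but
prevalence-unfiltered table, because rare taxa carry the richness signal.
No rarefaction is applied; sequencing depth instead enters the sensitivity
covariate model (`model2`) as a confounder, and `rarefy_counts()` exists for
robustness checks. Faith's PD uses the rooted convention (root included),
so a sample containing a single taxon scores its root-to-leaf path length.
Per-cohort z-scoring uses the n−1 SD, fixing the "SD units" of all effect
estimates.

PERMANOVA is computed directly from the distance matrix (Anderson's
formulation); the permutation p-value uses the add-one convention
p = (1 + #{F\* ≥ F}) / (1 + permutations) so p is never zero, with 999
permutations by default and a seeded generator. Pairwise group comparisons
are Benjamini–Hochberg adjusted. The E1-vs-control community test runs on
the two-group distance submatrix. PCoA reports all eigenvalues, forms
coordinates only from positive ones, expresses explained variance relative
to the positive spectrum, and fixes axis signs by making each axis's
largest-magnitude loading positive so output is reproducible.

## Network inference

**Pearson**: pairwise correlations of CLR profiles; edges need |r| > 0.3
and BH-FDR < 0.05 (p from the t statistic on r).

**SparCC**: basis variances are solved from the log-ratio variance matrix
T_ij = var(log x_i/x_j) under the sparse-correlation approximation, with up
to 20 rounds of excluding the strongest remaining pair (|ρ| > 0.1) from the
linear system; correlations are ρ_ij = (ω_i² + ω_j² − T_ij)/(2ω_iω_j).
Fractions use a pseudo-count rather than Dirichlet resampling. Significance
comes from a column-permutation null; because BH control across tens of
thousands of pairs needs finer p-value resolution than 100 permutations can
give directly, the permutation null is summarized by its per-pair mean and
SD and p-values are taken from the implied normal approximation. Edges need
|ρ| > 0.2 and FDR < 0.05.

**Neighborhood selection (SPIEC-EASI, mb variant)**: each CLR profile is
lasso-regressed on all others over a 20-point log-spaced penalty path
(smallest penalty = 0.1 × the largest), edges are symmetrized by the OR
rule, and the penalty is chosen by StARS: 50 subsamples of 80% of samples,
per-penalty edge instability 2θ(1−θ) averaged over pairs and monotonized,
then the least-regularized penalty with instability ≤ 0.05 is selected. No
further edge thresholding is applied — stability selection is the filter.
Note the 0.05 instability budget means pure-noise data can retain a small
percentage of stable spurious edges; the null-calibration tests bound that
density rather than demanding exact emptiness.

**Centrality and keystones.** Eigenvector centrality solves A c = λ c on
absolute edge weights. The leading eigenpair is computed on the largest
connected component, where Perron–Frobenius guarantees a non-negative
eigenvector; other nodes get centrality zero; the vector is normalized to
max 1. Keystones are nodes strictly above the empirical 95% quantile
(linear-interpolation type; ties at the quantile excluded — a network with
all-equal centralities has no keystones). Per-cohort calls from the three
estimators are combined by majority (≥ 2 of 3) by default; the combination
rule is configurable because combining "by combining the three methods" is
underdetermined — majority is the symmetric choice that neither lets one
noisy estimator inflate the set (union) nor lets it veto (intersection).
The cross-cohort shared set is a strict intersection, and the keystone
index is the per-sample sum of shared-keystone CLR values ("total
abundance" on the CLR scale is read as sum-of-CLR, since the pseudo-count
CLR sentence sits in the keystone-index description; CLR of summed counts
would be a different statistic).

## Association models and pooling

Group contrasts are OLS with reference-coded indicators (control group NE2
as reference) and the `model1` covariates: age, sex, BMI, hypoglycemic and
hypolipidemic medication (0/1). Disease models are maximum-likelihood
logistic fits adjusted for age, sex, and BMI, reported as odds ratios per
SD. All CIs are Wald/normal-approximation 95% intervals — the convention
when a paper reports 95% CIs without naming a method. Missing covariates
are handled complete-case per model with the n recorded. Sensitivity
regroupings: participants born after 1978 as a new reference; control plus
the 1956–1958 group as an age-balanced reference; the three in-utero groups
merged. Pooling is DerSimonian–Laird with Q, τ², and I² reported; ORs pool
on the log scale. DL with k = 3 cohorts is known to be slightly
anti-conservative; the coverage test budgets for that.

## The synthetic generator

`simulate_cohorts()` draws, per cohort, latent genus log-abundances from a
logistic-normal factor model, closes them by softmax, and samples counts by
a multinomial at a lognormal depth (meanlog log 40 000, sdlog 0.3,
emulating 16S read depths in the tens of thousands). The latent correlation
matrix plants `n_keystones` hubs, each correlated at `latent_correlation`
(default 0.7) with `hub_degree` satellites; hubs additionally share a
backbone factor with loading 0.8, so the keystone core is mutually
correlated (≈ 0.64 latent). The backbone reflects how real co-abundance
networks behave — one giant component with mutually central keystones — and
is also what makes hub recovery well-posed: compositional closure plus
multinomial sampling attenuates latent correlations substantially (a latent
0.36 reaches the CLR scale near 0.14, under every edge threshold), so a
weaker backbone would leave the planted clusters as disconnected components
in the *measured* network, and largest-component eigenvector centrality
could not rank hubs against each other.

Birth years are uniform on 1930–1990 by default (an optional weight table
mimics any empirical distribution); exposure effects are confined to 1959
births: keystone latent means drop by `famine_effect_delta` (default 0.8
SD) and a `diversity_effect` fraction (default 0.1) of the sample's rare,
non-network taxa are zeroed before the multinomial draw — zeroing is what
produces a deficit in *observed richness*, which mean shifts alone cannot.
The default 0.1 yields an E1 richness deficit of roughly 0.5–1 SD: large
enough to keep its sign stable given that a famine design leaves only ~2%
of participants in the 1959 group, small enough that the contrast is still
an estimation problem. Type 2 diabetes is drawn from a logistic model on
the standardized true (latent) keystone index with slope −0.14 log-odds per
SD (odds ratio ≈ 0.87) plus small age and BMI nuisance terms at a 12% base
rate. One RNG stream, seeded from the config, drives the whole dataset, so
a config is a complete recipe for its data.

What the generator does **not** emulate: taxonomic structure in the
phylogeny (trees are random), depth–composition coupling, batch and primer
effects beyond a per-cohort compositional offset, and any direct
richness → disease mechanism (diabetes depends on the keystone index only).
Passing tests therefore demonstrate that the pipeline recovers planted
structure through compositional count noise — not that the biological
claims hold in real cohorts.

## Validation strategy and problem sizes

Every numerical kernel is checked against an independent oracle: PERMANOVA
against `vegan::adonis2` and exhaustive permutation enumeration at n = 6;
PCoA against exact reconstruction of Euclidean configurations; eigenvector
centrality against shifted power iteration on random graphs; BH against a
hand-rolled implementation; logistic betas against the 2×2 cross-product
ratio; DL pooling against hand arithmetic and `metafor`. Null calibration
uses 500 PERMANOVA and 200 linear-contrast replicates. Parameter recovery
runs ten simulated cohorts of 500 samples × 300 genera with 15 planted hubs
(15 ≈ the 5% of 300 genera that the 95%-quantile rule tags, so recall and
precision are both attainable in principle) and requires mean recall ≥ 0.8
and precision ≥ 0.5 for the majority-combined keystone calls; the planted
exposure deficit must carry the correct sign in all three default cohorts
with the pooled CI covering the realized latent contrast, and the planted
disease odds ratio must fall inside the Wald CI at n = 5000. For the
multi-seed experiments the stability-selection settings are scaled to 10
StARS subsamples over a 12-point path and 50 SparCC permutations; spot
checks at the full defaults gave identical keystone calls.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  simulation = simulation_config(seed = 7),
  sparcc_bootstrap = 50, stars_subsamples = 10, spieceasi_nlambda = 12,
  seed = 7)
report <- run_pipeline(cfg)
report$shared_keystones          # recovered shared keystone taxa
report$truth_comparison          # recall/precision against the planted hubs
subset(report$pooled$linear,
       outcome == "keystone_index" & term == "E1_vs_NE2")
```

## Known limitations

* SparCC p-values use a normal summary of the permutation null; extremely
  heavy-tailed null distributions would distort tail p-values, though FDR
  decisions at 0.05 are insensitive in practice.
* Only the `mb` (neighborhood selection) variant of sparse inverse
  covariance is implemented; graphical-lasso would need a dedicated solver.
* The PERMANOVA is unadjusted for covariates (as in the source design);
  confounding of community-level tests must be addressed by design or by
  the regrouping sensitivity schemes.
* DL pooling of three cohorts inherits the usual small-k anti-conservatism;
  treat pooled CIs as approximate.
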