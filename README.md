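# gutkeystone

Cross-cohort gut-microbiome association analysis around keystone taxa, for
epidemiologists studying early-life exposures — in particular famine
natural experiments — and adult cardiometabolic disease.

Adults sampled decades after the 1959–1961 Chinese famine can be classified
by birth year into exposure windows: the group born in 1959 (code `E1`) was
exposed in utero and through the first two postnatal years — the first 1000
days of life — while those born 1962–1964 (`NE2`) form the no-exposed
control group. This package implements the full analysis chain that links
such an exposure to the adult gut microbial ecosystem and onward to type 2
diabetes, with every stage testable on synthetic data:

* **Compositional preprocessing** — depth/birth-year/antibiotic sample
  filters, 10% prevalence filter, multiplicative zero replacement, and the
  centered log-ratio transform
  `clr(x)_i = log x_i − (1/D) Σ_k log x_k`.
* **Diversity & community structure** — observed richness, Shannon H,
  Pielou J = H / log S, Faith's PD; Bray–Curtis dissimilarity
  `d(a,b) = Σ|x_ai − x_bi| / Σ(x_ai + x_bi)`, principal coordinates, and
  PERMANOVA (999 seeded permutations, add-one p-value, pairwise BH).
* **Co-abundance networks** — three estimators per cohort: Pearson on CLR
  (|r| > 0.3, FDR < 0.05), SparCC (log-ratio variance basis solve,
  |ρ| > 0.2, FDR < 0.05), and neighborhood-selection sparse inverse
  covariance with StARS stability selection.
* **Keystone taxa** — eigenvector centrality from `A c = λ c` (leading
  eigenpair of the adjacency on its largest connected component); keystones
  are nodes above the empirical 95% centrality quantile; per-cohort method
  calls combine by majority, cohorts intersect into a shared set, and the
  **keystone taxa index** is the per-sample sum of shared-keystone CLR
  values (pseudo-count 1), z-scored within cohort.
* **Association & meta-analysis** — covariate-adjusted linear group
  contrasts (SD units) and logistic disease models (OR per SD), pooled by
  DerSimonian–Laird random effects
  (τ² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw))).
* **Synthetic multi-cohort generator** — logistic-normal-multinomial counts
  with a planted hub-structured correlation network, planted first-1000-days
  deficits, and a planted index→diabetes odds ratio, so recovery of every
  quantity can be measured against ground truth.

## Worked example

Simulate three cohorts of 400 samples × 120 genera with six planted hub
(keystone) genera, run the whole pipeline, and pool across cohorts:

```r
library(gutkeystone)

cfg <- pipeline_config(
  simulation = simulation_config(cohort_sizes = c(400, 400, 400),
                                 n_genera = 120, n_keystones = 6,
                                 hub_degree = 8, seed = 7),
  sparcc_bootstrap = 50, stars_subsamples = 10, spieceasi_nlambda = 12,
  seed = 7)
report <- run_pipeline(cfg)

report$shared_keystones
#> [1] "g031" "g042" "g066" "g083" "g092" "g103"
report$truth_comparison$planted_keystones
#> [1] "g031" "g042" "g066" "g083" "g092" "g103"

subset(report$pooled$linear,
       outcome == "keystone_index" & term == "E1_vs_NE2")
#>          outcome      term k       beta    ci_low    ci_high     p_value I2
#> 2 keystone_index E1_vs_NE2 3 -0.7667366 -1.262281 -0.2711923 0.002424753  0

subset(report$pooled$t2d, term == "keystone_index_per_sd")
#>                    term k odds_ratio or_ci_low or_ci_high   p_value
#> 2 keystone_index_per_sd 3  0.9297893 0.7812838   1.106523 0.4122682
```

Reading the output: the three-method majority keystone calls, intersected
across cohorts, recover exactly the six planted hubs. The pooled linear
contrast says participants born in 1959 sit 0.77 SD below the control group
on the keystone index (95% CI −1.26 to −0.27) — the planted deficit, with
the correct sign and covered truth. The pooled odds ratio per SD of index is
0.93 and its CI spans 1: at 1200 samples the planted OR of 0.87 is inside
the interval but not yet significant, which is the honest small-sample
answer (the disease association is powered at cohort-consortium scale, not
at demo scale).

A thin command-line wrapper for both steps lives at
`inst/scripts/gutkeystone-cli.R` (`simulate` and `run-all` subcommands over
a JSON config).

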