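# promodyn

Promoter tiling-array occupancy dynamics, transcription-factor
co-occupancy, and knockout epistasis analysis.

## What it is for

ChIP-chip promoter tiling arrays measure, for every gene, a
log2(ChIP/input) ratio at probes tiling a fixed window around the TSS
(−3250 to +750 bp here). When the immunoprecipitated factor is a
stress-responsive chromatin regulator — the motivating system is the
histone deacetylase Sirt6 moving across promoters within minutes of TNF-α,
in partnership with the NF-κB subunit RelA — three questions follow:
where/when is each factor bound, do the two factors co-occupy promoters
(and does one depend on the other), and what does that co-occupancy do to
gene expression in single and double knockouts?

`promodyn` answers them as a reusable, fully tested pipeline for anyone
analyzing probe-level promoter-array ChIP time courses with knockout
controls:

* **Normalization** — Tukey biweight centering of each sample
  (`normalize_biweight()`).
* **Peak calling** — sliding fragment-size windows, candidate mean-signal
  rule, merging (`call_peaks()`); permutation-based FDR with step-down
  monotonicity (`estimate_fdr()`); FDR-threshold calibration against known
  targets (`calibrate_fdr_threshold()`).
* **Target mapping** — peaks → genes within ±4 kb promoter flanks,
  knockout-control subtraction, time-course unions (`peaks_to_genes()`,
  `subtract_knockout_control()`, `union_over_timepoints()`).
* **Occupancy analysis** — binary occupancy matrix, temporal dynamics
  labels (periodic / baseline-vacated / induced / ...), log-space
  hypergeometric co-occupancy, binding-site distances, RelA-dependence
  classes (abrogated / reduced / independent).
* **Expression epistasis** — detection filtering, normalization to
  untreated wild type, rule-based classes (All-Up, TNF-Up, Zero-Up,
  Inverse, RelA-blocked-Sirt6) with explicit fold cutoffs.
* **Enrichment** — hypergeometric gene-set enrichment with
  Benjamini–Hochberg correction (GMT collections).
* **Synthetic data** — a generator that plants all of the structure above
  (`sim_params()`, `simulate_*()`), so every stage is benchmarked against
  known ground truth.

The core statistic for co-occupancy is the upper-tail hypergeometric
probability computed in log space: for a universe of N promoters with K
targets of one factor and n of the other, the overlap k is scored by
P(X ≥ k), X ~ Hypergeometric(N, K, n). On the published genome-wide counts
(N = 21,249, K = 5050, n = 2738, k = 1481) this gives log10 p ≈ −300,
i.e. far beyond the p < 2.5×10⁻²⁸⁶ headline, with overlap percentages
54% and 29%.

## Worked example

```r
library(promodyn)

params <- sim_params(n_genes = 500)      # study-scale proportions, 500 promoters
res <- run_pipeline(params, default_config(), seed = 1)

length(res$sirt6_union$genes)            # 119 Sirt6 targets
length(res$rela_union$genes)             # 64 RelA targets
length(res$shared_genes)                 # 35 co-occupied promoters
round(res$overlap$log10_p, 1)            # -8.1 : overlap beyond chance
table(res$dynamics)
#> baseline_vacated  induced  periodic  unbound
#>               16       16        87      381
table(res$dependence$label)
#> abrogated independent     reduced
#>        17          14           4
res$class_counts$counts
#>    AllUp  TNFUp  ZeroUp  Inverse  RelABlockedSirt6  Unclassified
#>        4     10       1        1                 3             7
round(unlist(res$metrics), 3)
#> peak_sensitivity  peak_fdp  frac_shared  frac_abrogated  frac_within_500  epistasis_recovery
#>            1.000     0.000        0.547           0.486            0.657               0.962
```

Reading the output: of 500 simulated promoters the pipeline recovers 119
Sirt6 and 64 RelA targets whose overlap (35 genes) has log10 p ≈ −8.1
against the promoter universe; most bound promoters follow the periodic
on/off/on occupancy pattern; among co-occupied, WT-bound genes, 17 lose
Sirt6 binding entirely in RelA-null cells ("abrogated"); 15 of the
classified expression profiles fall into the three antagonistic classes.
The `metrics` entry scores everything against the planted truth: here every
planted site is found at FDR ≤ 0.1 with no false peaks, and the planted
co-occupancy (0.54), dependence (0.49) and site-distance (0.65) fractions
are recovered within a few percent.

A command-line front end with the same stages
(`simulate`, `callpeaks`, `targets`, `dynamics`, `cooccupy`, `epistasis`,
`enrich`, `run-all`) is installed at
`system.file("scripts", "promodyn.R", package = "promodyn")`.

## Layout

```
R/                  pipeline stages (one file per module)
src/                C++ window scan and permutation null (Rcpp)
tests/testthat/     unit, property and acceptance tests with independent oracles
vignettes/          methods vignette: models, rules, parameter rationale
inst/scripts/       command-line front end
scripts/            acceptance script (see above)
```
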