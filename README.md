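# methylpanel

Genome-wide DNA-methylation analysis of fibrotic progression in
prefibrotic primary myelofibrosis (pre-PMF), as a tested, reusable R
pipeline.

Pre-PMF is a myeloproliferative neoplasm in which some patients progress
to overt bone-marrow fibrosis (FP) while others remain stable (SD), and
the two courses are hard to tell apart at diagnosis. `methylpanel`
implements the analysis chain for asking whether EPIC-style 850k
methylation profiles of bone-marrow trephines separate the two groups:

* **Preprocessing** — detection-p filtering (p > 0.1), BMIQ beta-mixture
  intra-sample normalization of type II probes, ComBat batch correction on
  M-values with the group protected, and an SVD confounder screen.
* **Differential methylation** — moderated-t DMPs on M-values
  (empirical-Bayes variance shrinkage, BH FDR ≤ 0.1, no beta cutoff),
  bump-hunting DMRs (maxGap 250 bp, |coefficient| cutoff at the 0.99
  quantile, permutation null, FDR ≤ 0.05), Wallenius probe-bias-corrected
  GO-style enrichment, and centroid-linkage heatmap ordering.
* **Minimal CpG panels** — exact branch-and-bound subset selection
  maximizing the two-group separation criterion τ² = 1 − Λ, with
  Λ = det(E)/det(T) the Wilks statistic of within- vs total scatter;
  linear discriminant classification `w ∝ Σ⁻¹(μ_FP − μ_SD)` with class
  probabilities and confidence bands on LD1; stratified fivefold repeated
  cross-validation with selection inside each fold.
* **Copy-number profiles** from combined probe intensities against an SD
  reference cohort (log2 ratios, recursive binary segmentation, gain/loss
  calls at |log2| ≥ 0.5).
* **Epigenetic age** — linear clock scoring (PhenoAge-style coefficients
  read from CSV), EA > CA contingency with the uncorrected Pearson χ²,
  and group comparison of EA − CA by Mann–Whitney.
* **Cohort statistics** — hyper/hypomethylation extremes accounting
  (β > 0.8 / β < 0.1), rank and contingency tests, and Cauchy-prior MAP
  logistic regression that stays finite under complete separation.
* **Synthetic cohorts** — a first-class generator that plants DMPs, DMRs,
  copy-number segments, batch effects, probe failures and an age-linear
  clock with full ground truth, so every stage is testable end to end.

Assay matrices (β, intensities, detection p) are plain samples × probes
matrices; every analysis result is a tibble, so stages chain with the
pipe, and the fitted panel model has `tidy()`/`glance()` methods and
ggplot2 plot functions (`plot_dmp_heatmap()`, `plot_ld1()`,
`plot_cna_profile()`, `plot_age_results()`).

## Worked example

```r
library(methylpanel)

cohort <- generate_cohort(sim_config(
  n_fp = 16, n_sd = 17, n_probes = 4000, n_plates = 2,
  dmp_spec = list(list(probes = 1:25, delta_beta = 0.12)),
  clock_spec = list(probes = 101:120, weight = 5, intercept = 0, noise_sd = 2),
  seed = 42))
cohort
#> <synthetic_cohort> 33 samples x 4000 probes (16 FP / 17 SD)
#>   planted: 25 DMPs, 0 DMRs, 0 CNA segments, 20-probe clock

clock <- clock_model(0, setNames(rep(5, 20), cohort$annotation$probe_id[101:120]))
res <- run_pipeline(cohort,
                    pipeline_config(dmr_n_perm = 50, candidate_pool = 20,
                                    k_max = 6, cv_repeats = 2, seed = 42),
                    clock = clock)

head(res$dmp, 3)
#> # A tibble: 3 × 10
#>   probe_id   mean_fp mean_sd delta_beta moderated_t    df        p        q
#> 1 cg00000023   0.999  0.933      0.0663        34.4  35.2 1.08e-28 4.25e-25
#> 2 cg00000002   0.999  0.933      0.0658        33.5  35.2 2.69e-28 5.31e-25
#> 3 cg00000007   0.218  0.0307     0.187         22.9  35.2 9.87e-23 1.30e-19

res$panel
#> <panel_model> 1-CpG linear discriminant
#>   probes: cg00000007
#>   projected means: FP -3.062; SD 3.062  threshold: -0.009899
#>   training separation: complete
mean(res$cv$accuracy)
#> [1] 1
table(res$cna$segments$call)
#> neutral
#>      23
res$filter_report$n_evaluable
#> [1] 3939
```

Reading the output: the top DMPs are planted probes recovered at
vanishingly small q; on this strongly-shifted cohort a single CpG
(`cg00000007`, planted Δβ ≈ 0.19) already separates the groups perfectly,
so the minimal panel has size 1 and cross-validated accuracy 1.0; no
copy-number segment reaches the |log2| ≥ 0.5 call threshold (none was
planted); 3939 of 4000 probes survive detection-p filtering at the
configured 0.5% failure rate. The epigenetic-age stage (`res$age`,
`group_age_difference()`) recovers ages from the planted clock with
r ≈ 0.98.

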