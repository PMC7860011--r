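---
title: "Methods: methylation analysis of fibrotic progression in pre-PMF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation analysis of fibrotic progression in pre-PMF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`methylpanel` implements the analysis chain used to ask whether genome-wide
DNA methylation, measured on EPIC-style 850k arrays from bone-marrow
trephines, can discriminate prefibrotic primary myelofibrosis (pre-PMF)
patients who later progress to overt fibrosis (FP) from patients with
stable disease (SD). The chain is: detection-p quality filtering, BMIQ
intra-sample normalization, ComBat batch correction with an SVD confounder
screen, moderated-t differential methylation (DMPs), bump-hunting
differentially methylated regions (DMRs), probe-bias-aware gene-set
enrichment, exact minimal CpG-panel selection by branch and bound on the
tau-squared criterion with linear discriminant classification,
methylation-derived copy-number profiles, epigenetic-clock age statistics,
and cohort-level methylation accounting. Because the original patient
cohort is not bundled, a synthetic-cohort generator with known planted
structure provides ground truth for every stage.

## The synthetic cohort generator

`generate_cohort()` emulates the features of array methylation data that
the downstream stages actually exercise:

* **Baseline beta values** follow a three-state mixture: each probe is
  assigned to an unmethylated (Beta(2, 18)), hemimethylated (Beta(12, 12))
  or methylated (Beta(18, 2)) component with weights 0.35/0.15/0.5, and
  per-sample values are drawn from a Beta distribution concentrated around
  the probe mean (precision 80). The three-state baseline matches the
  mixture model BMIQ assumes.
* **Probe chemistry**: 84% of probes are Infinium type II (the EPIC
  proportion) and their values are compressed toward 0.5 by a factor 0.75,
  reproducing the reduced dynamic range that motivates BMIQ.
* **Group effects** (DMPs/DMRs) are additive on the beta scale for FP
  samples, then clipped to [0, 1].
* **Plate batch effects** are per-plate, per-probe Gaussian shifts applied
  on the logit scale (default sd 0.25), which keeps beta inside (0, 1) and
  matches the M-value convention of the correction step.
* **Intensities** satisfy beta = M/(M + U + 100) up to 3% lognormal channel
  noise, with total intensity around 4000. Planted copy-number segments
  multiply both channels by `2^shift` for the chosen samples.
* **Clock signal**: clock probes are linear in chronological age with a
  configurable age-scale noise, so the matching linear clock recovers age.
* **Detection failures**: a configurable fraction of sample-probe cells
  (default 0.5%) get detection p inflated into (0.2, 1).
* **Manifest geometry**: probes are spread over 22 autosomes at 50 kb
  spacing (far above the 250 bp region gap, so background probes cannot
  chain into regions); planted DMR clusters are laid down at their own
  spacing below the gap.

The default cohort is 16 FP / 17 SD on two plates, the sample sizes of the
motivating study; the classification design replica uses 12 FP / 10 SD for
training and 4 FP / 7 SD for testing. Sample ages are uniform on 45–80
years, the age range typical of pre-PMF diagnosis.

What the generator does **not** emulate: sex chromosomes, SNP-affected
probes, cell-composition gradients, spatially varying probe density, or
raw IDAT-level artifacts. Passing tests therefore demonstrate algorithmic
correctness against planted truth, not robustness to every artifact of
real arrays.

## Preprocessing

**Detection filtering** uses the detection p-value threshold 0.1. Samples
failing more than 10% of probes are excluded first, then probes failing in
more than 5% of remaining samples. The study states only the p-threshold;
the two fractions follow common array-QC practice and are exposed as
configuration.

**BMIQ** fits the 3-state beta mixture by EM separately to the type I and
type II probes of each sample (k-means initialization at centers
0.1/0.5/0.9, method-of-moments M-step, relative log-likelihood tolerance
1e-5, at most 1000 iterations, ties in state assignment resolved toward
the lower-mean state). Type II unmethylated and methylated probes are
quantile-mapped onto the corresponding type I state distributions
(`qbeta(pbeta(x, a2, b2), a1, b1)`); the middle state is carried by a
monotone linear interpolation between the mapped boundary states. Type I
probes pass through unchanged; the transform is monotone within type II
and bounded in [0, 1].

**ComBat** runs on M-values, with beta clamped to [1e-3, 1-1e-3] before
the logit — a bounded transform with negligible bias at the scale of
array noise. The parametric empirical-Bayes location/scale model is the
one implemented in `sva::ComBat`; the group (FP/SD) enters as a protected
covariate. A batch aliased 1:1 with the protected covariate is rejected as
inestimable. Following the study design, batch correction feeds only the
statistics branch; **classification always uses the non-corrected
matrix**.

**SVD screen**: the top `min(20, n-1)` left singular vectors of the
column-centered beta matrix are tested against each sample covariate
(Kruskal–Wallis for categorical, Spearman for numeric). Raw p-values are
reported per component. For the variable-level confounder flag we use
BH-adjusted q < 0.05 rather than raw p < 0.05: with 20 components per
variable, raw-p flagging would mark independent noise as confounding in
roughly two thirds of cohorts, which contradicts the screen's purpose;
the BH flag keeps the screen-wide false-flag rate near 5% while a real
plate effect is still detected essentially always.

## Differential methylation

`fit_dmp()` tests the group contrast per probe on M-values and reports
effects as delta-beta, trading variance stabilization in the test for
interpretability in the report. Residual variances are shrunk toward a
common prior estimated by moments matching on log variances (prior df
capped at 100); the moderated t has `residual df + prior df` degrees of
freedom. Setting the prior df to zero recovers the ordinary pooled-variance
t-test exactly, and the estimated-prior path agrees with the independent
limma implementation to within rounding in the test suite. Significance is
purely FDR-based (BH, q <= 0.1) with no delta-beta cutoff. "Top N" probes
are the N smallest p-values, ties resolved by larger |t| then probe id.

`find_dmrs()` follows the bump-hunting recipe with maxGap 250 bp and
cutoff quantile 0.99 of |coefficient| (the quantile reading of the cutoff;
an absolute-value cutoff would be an alternative configuration). Candidate
bumps are maximal same-sign runs above the cutoff inside gap clusters,
scored by area. The null distribution pools bump areas from label
permutations (default 250); we use the add-one-smoothed permutation
p-value `(1 + b)/(1 + B)` rather than the bare fraction so that no bump
gets p = 0 from a finite null — a conservative choice that matters only
at resolution 1/B. Regions are kept at BH q <= 0.05.

`gene_set_enrichment()` corrects the per-gene probe-count selection bias
with a Wallenius noncentral hypergeometric model: the odds parameter of a
term is the mean probe count of its genes relative to the rest of the
universe, and the tail probability is evaluated by numerical integration
of the Wallenius density. With equal probe counts everywhere this reduces
to the ordinary hypergeometric test.

Heatmap ordering uses agglomerative clustering with **centroid linkage**
on squared Euclidean distances of beta values (the convention under which
centroid linkage is well defined); height inversions in the tree are
accepted as a known property of centroid linkage.

## Minimal-panel selection and classification

For two groups, Wilks' Lambda on a probe subset is
`det(E)/det(T)` (within-group over total scatter) and the separation
criterion is `tau^2 = 1 - Lambda` — the general `1 - Lambda^(1/l)` with
`l = min(groups - 1, k) = 1`. `leaps_and_bounds_select()` finds the exact
global optimum of tau^2 over subsets of size k by depth-first branch and
bound, pruning with the monotone bound `tau^2(S) <= tau^2(S ∪ R)`:
a partial subset is abandoned when even its union with the whole remaining
pool cannot beat the incumbent. Candidates enter in decreasing order of
single-probe tau^2 so a strong incumbent forms early. Equal-tau^2 ties
are resolved lexicographically by probe id. The suite verifies exact
agreement with exhaustive enumeration over hundreds of random instances.

`minimal_panel()` applies the published preference for fewer features: for
k = 1, 2, ... it fits an LDA on the tau^2-best subset and returns the
first k with zero training misclassifications, else flags the largest
model non-separating. The candidate pool is the top 40 DMPs by p-value by
default (the study does not state its pool size; this is configuration,
not fidelity). The LDA direction is `pooled-covariance^-1 (mu_FP - mu_SD)`
with a ridge of `1e-6 * trace/k` when near-singular, scaled to unit
projected within-group variance and signed so the FP centroid projects
negative (matching the display convention of FP on the left). The decision
threshold is the midpoint of projected class means shifted by the log
prior ratio; posteriors come from the two-class Gaussian discriminant on
the projected scale, with confidence bands at class probability 0.95
(high) and 0.5 (low). Cross-validation is stratified five-fold, repeated,
with selection and fitting redone inside every training fold.

A published six-CpG panel with its discriminant coefficients ships as a
JSON fixture (`inst/extdata/pmf_6cpg_panel.json`) for serialization and
lookup tests only. Its coefficients cannot be reproduced here — they
derive from the original cohort, whose centering and scaling conventions
are not recoverable from the printed table — so the fixture is treated as
opaque reference data.

### The certified train/test replica

The end-to-end classification check needs a cohort whose *minimal* panel
size is known, not assumed. `generate_panel_design_cohort()` plants
`k` signal probes that share `k - 1` latent noise factors whose loadings
are orthogonal to the all-ones signal direction: each probe alone (and
every subset smaller than `k`) retains factor noise and cannot separate
the groups, while the full `k`-probe discriminant cancels the factors and
separates cleanly. Because this is a statement about a random draw, the
generator certifies each candidate instance by exhaustive subset
enumeration (independent of the branch-and-bound code path) plus an LDA
separation check, and redraws until certification succeeds. The latent
factors are the synthetic analogue of shared technical or cell-composition
noise, the realistic reason a panel outperforms its individual CpGs.

## Copy-number profiles

Combined intensity is the channel sum M + U. The query group's per-probe
median is compared with the per-probe median of the reference (SD) group
as `log2(query/reference)`, then recentered so the sample's median
autosomal log2 ratio is zero — whole-genome ploidy is unobservable for a
relative assay. Segmentation is recursive binary splitting: the split
maximizing the two-sample t-statistic between flanks is accepted when its
p-value is below 0.01 and both sides keep at least 10 probes; segment
values are probe means (conserved exactly). Gains and losses are called at
|log2| >= 0.5, boundary inclusive. Binning is omitted because synthetic
manifests are sparse; per-probe segmentation with `min_probes = 10` plays
the same role, and no GC correction is applied.

## Epigenetic age

A clock is an intercept plus per-probe weights in years per beta unit —
coefficients are data, read from CSV, never hard-coded; tests use planted
synthetic clocks. EA is the linear score over available clock probes, with
cohort-mean imputation (or a strict error) for missing probes and a
configurable 80% coverage floor. The EA-vs-CA contingency counts strict
excess only (`EA - CA > 0`; a tie is "not larger") and is tested with the
uncorrected Pearson chi-square, the variant that reproduces the printed
p = 0.021 from the printed 9/16 vs 3/17 table. Group-level acceleration is
compared with a two-sided Mann–Whitney test on EA − CA.

## Cohort statistics

Methylation extremes are counted per sample-probe observation by default
(beta > 0.8 hyper, beta < 0.1 hypo, matching pooled-histogram accounting),
with a per-probe-mean mode for robustness checks; the report gives the
percent excess of FP over SD in both tails. The Mann–Whitney test is exact
for min(n) <= 8 without ties and otherwise uses the tie-corrected normal
approximation without continuity correction. The multivariate analysis
uses maximum-a-posteriori logistic regression with independent Cauchy
priors (scale 2.5 on covariates standardized to sd 0.5, binary covariates
centered, intercept scale 10): estimates stay finite under the complete
separation that 33-sample cohorts produce by chance, Wald z and p come
from the Hessian at the mode, and the fit converges to the MLE as the
prior widens. Incomplete clinical covariates (cell counts, hemoglobin) are
fitted one at a time on complete cases, with no imputation.

## Numerical choices and degenerate inputs

* Beta-to-M clamp at [1e-3, 1-1e-3]; probe variances floored at 1e-10 and
  flagged when within-group variance is exactly zero.
* Ridge `1e-6 * trace/k` on scatter and covariance matrices near
  singularity; a still-singular total scatter is a "degenerate subset"
  error.
* EM: k-means initialization, relative tolerance 1e-5, max 1000
  iterations, error with the log-likelihood trace on non-convergence.
* Permutation p-values use add-one smoothing; `n_perm < 10` is rejected.
* Identical class means give a null discriminant direction and
  prior-valued posteriors rather than an error.
* A constant copy-ratio stretch is never split; an exact level shift is
  always split.

## Problem sizes

The test and acceptance workloads run cohorts of 16–33 samples and
700–4000 probes, 20-seed replications for stochastic properties, 100
random instances for the branch-and-bound/enumeration equivalence, and
250-permutation DMR nulls scaled to 25–100 permutations inside tests.
These sizes were chosen to make every property measurable with comfortable
Monte-Carlo margins on a desktop machine.

## Known limitations

* BMIQ's middle-state interpolation is linear between mapped boundary
  states; the original formulation uses a slightly different dilation but
  shares its monotonicity and endpoints.
* The DMR finder does not smooth coefficients before thresholding, so
  single extreme probes can form one-probe regions; the permutation null
  accounts for them, but a smoothing pre-step would suppress them earlier.
* The cohort-level evaluability fraction depends on the configured failure
  rates and is reported as computed; it is not calibrated to any external
  count.
* Copy-number segmentation is deterministic recursive splitting, not
  permutation-pruned CBS; on desk-scale profiles the two agree on clear
  breakpoints but can differ on marginal ones.
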