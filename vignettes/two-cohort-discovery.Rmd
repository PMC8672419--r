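---
title: "Two-cohort transcriptomic discovery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-cohort transcriptomic discovery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trendmeta)
options(trendmeta.verbose = FALSE)
```

`trendmeta` implements a discovery pipeline for staged disease that joins
two independent lines of transcriptomic evidence: a blood cohort sampled
along an ordered clinical severity scale, and a collection of public
case/control tissue datasets from heterogeneous microarray platforms. This
vignette is the package's account of the underlying statistics, the
choices made where the methodology was genuinely open, and what the
bundled simulations do and do not demonstrate.

## 1. The ordered-trend screen (blood cohort)

### Model and assumptions

Per gene, we ask whether expression shifts monotonically across the
ordered stages (default ordering `HC < D1 < D2 < D3 < ESRD`, the
albuminuria-staged severity scale). The Jonckheere–Terpstra statistic

$$ J \;=\; \sum_{i<j}\;\sum_{x \in G_i,\; y \in G_j}
   \Big[\, \mathbf 1(x<y) + \tfrac12\,\mathbf 1(x=y) \,\Big] $$

sums Mann–Whitney counts over all ordered group pairs. It is rank-based:
no distributional assumption beyond exchangeability under the null, and
invariance to any strictly increasing transform of the data (so log2 vs
linear scale is immaterial). Under the permutation null,

$$ E[J] = \frac{N^2 - \sum_i n_i^2}{4}, \qquad
   \operatorname{Var}[J] =
   \frac{N^2(2N+3) - \sum_i n_i^2(2n_i+3)}{72} $$

without ties; with ties we use the exact three-term tie-corrected
permutation variance computed from the tie-group multiplicities, which the
test suite verifies against full-enumeration moments to 1e-10.

### p-value computation

Three methods, cross-validated against each other on small data:

* **exact** — full enumeration of all distinct assignments of the observed
  values to the groups (refused above 10⁶ assignments, with a pointer to
  the Monte-Carlo method). The one-sided p is the fraction of assignments
  with $J^* \ge J$ (increasing) or $J^* \le J$ (decreasing).
* **montecarlo** — permutation with the add-one estimator
  $(b+1)/(n_{\text{perm}}+1)$ (default 10,000 permutations), so a reported
  p is never 0 and is honest about resolution.
* **asymptotic** — $z = (J - E[J])/\sqrt{\operatorname{Var}[J]}$ with the
  tie-corrected variance, no continuity correction. At the cohort's sizes
  (10/11/7/5/7, N = 40) the lattice spacing of J is tiny relative to the
  null SD (~42), and the simulated type-I error at α = 0.05 falls well
  inside [0.040, 0.060] per direction.

Degenerate genes (zero permutation variance, e.g. all values tied) are
flagged and given p = 1 rather than NA, so they can never enter a
significance list silently.

### Direction handling

The screen runs both one-sided tests per gene and reports separate
up/down lists, mirroring how such screens publish separate
increasing/decreasing counts. Each gene is assigned the direction with
the smaller one-sided p, then thresholded at α; for any α ≤ 0.5 this is
identical to thresholding each side independently (a gene cannot be
one-sided-significant both ways), and it keeps the two lists disjoint for
all α, including the exhaustive α = 1 case. Screening p-values are raw —
the screen is a ranking device — with BH-adjusted columns emitted for
information.

The default stage set for the headline ranking is `D1 < D2 < D3` (the
albuminuria levels proper, as used in ranked result tables); the screen
accepts any ordered subset, and `NULL` means "all stages present". The
simulations in this package plant and screen trends across the full
five-stage ordering, because disease severity in the emulated study spans
healthy controls through end-stage disease.

## 2. The meta-analysis screen (tissue collection)

Each dataset contributes a per-probe **signed Z**: a case-vs-control
Welch t-test gives the upper one-tailed $p_+ = P(T > t)$, and
$z = \Phi^{-1}(1 - p_+)$. This encodes direction automatically (cases
above controls ⇒ z > 0) and makes a null probe exactly N(0,1) by the
probability integral transform. Welch (unequal variance) is the default
because platform noise differs across case/control groups of public
datasets; the pooled-variance variant is available by flag and both are
checked against `stats::t.test`.

Probes are collapsed to genes **before** combination, by default keeping
the probe with the largest |z| per gene (best-probe summarization; ties
broken by lexically smallest probe id for determinism). The `median_z`
rule is available for sensitivity analysis. Collapse-then-combine mirrors
the platform-reannotation workflow in which probe identifiers are mapped
to gene identifiers before cross-platform comparison.

Gene-level Z-scores are combined by the weighted Z-method,
$Z_{\text{meta}} = \sum_d w_d z_d / \sqrt{\sum_d w_d^2}$ with
$w_d = \sqrt{n_d}$ (dataset total sample size), the standard
sample-size-weighted Stouffer/Liptak choice. Genes absent from some
platforms are combined over the datasets that observe them, with the
count reported. Screening calls use |Z| > 5 — under the null the expected
number of such calls in 10,000 genes is $2\Phi(-5)\cdot 10^4 \approx
0.006$, i.e. effectively a no-false-positive threshold.

A note on calibration testing: with multiple probes per gene the max-|z|
collapse inflates the null |Z| of a gene by construction (it is a maximum
over correlated draws). The package's null-calibration checks therefore
run at one probe per gene, so they test what they intend to test — the
normality of the weighted combination — rather than the known and
intentional bias of best-probe summarization.

## 3. Overlap and enrichment

The two screens are intersected inside the universe of genes testable in
**both** cohorts (the intersection of the blood matrix's genes with the
union of genes any tissue platform maps to) — the only universe in which
membership in both lists is defined. The overlap size k is scored by the
upper-tail hypergeometric probability, accumulated in log space; the
implementation agrees with exact combinatorial sums (and with
`stats::phyper`) to 1e-12 relative error across the tested range. The
default intersects up-in-blood with up-in-tissue (the concordant
signature of interest in the emulated study); down/down and pooled modes
are available. Ranked overlap records sort by trend p, ties by meta p.

Over-representation analysis against GMT collections uses the same
hypergeometric tail per set, restricted to the universe, with
Benjamini–Hochberg adjustment across sets and a pass flag at q ≤ 0.05
(Bonferroni by flag). This is a deliberately generic, transparent
replacement for proprietary pathway tooling: the inputs are ordinary GMT
files supplied by the user.

## 4. Two-color normalization and QC

* **Within-array loess** (`M' = M - \hat f(A)`, span 0.3, via limma's
  local regression): the span is the conventional MA-normalization
  default; the method's name is standard but parameters rarely published,
  so span is configurable and logged. A constant-A array cannot support a
  regression on A and falls back to median-centering with a warning.
  Applying the smoother twice moves residuals only by the smoother's
  wiggle on noise (≈ noise SD / √(effective window n)), which is the
  basis of the idempotency check at low residual noise.
* **Between-array aquantile**: A-values are quantile-normalized across
  arrays (sorted values replaced by across-array means, average-rank rule
  for ties), M untouched. After normalization the A-quantile functions
  are identical by construction, which the tests assert exactly.
* **PCA outlier flagging**: samples are scored on (PC1, PC2) of the
  centered/scaled gene matrix, robustly standardized per axis
  (median/MAD), and flagged when their distance from the robust centroid
  exceeds `threshold_sd` (default 4). Under a null Gaussian cloud of 40
  samples the flag rate is ≪ 5%; three samples displaced by many SD are
  flagged exactly. The default of 4 makes an inspection-based removal of
  gross outliers reproducible and logged; flagging never removes anything
  by itself.
* **ANOVA filter**: classical equal-variance one-way ANOVA per gene
  (vectorized; verified against `stats::oneway.test`), the simplest
  reading of "ANOVA" as a clustering pre-filter. Constant genes are
  excluded with a warning.
* **Hierarchical clustering**: samples are sorted lexically before the
  distance computation so tree topology is invariant to input column
  order, including tie-breaks.

Outlier handling order is normalize → QC by default; the package keeps
the two stages separate so either order can be scripted.

## 5. The synthetic-data generator

The generator emulates the *study conditions*, not any particular
dataset:

* **Blood cohort**: five ordered stages at n = 10/11/7/5/7. Gene g in
  sample s is $N(\mu_g + s_g\,\delta\,\sigma\,t_s,\ \sigma^2)$ with
  baseline $\mu_g \sim N(7, 1.5^2)$ (log2 scale), noise σ = 1, trend step
  δ = 0.5 σ per stage for the 50 planted trend genes
  ($s_g \in \{+1,-1\}$), and $t_s$ the stage index within the configured
  trend stage set (stages outside the set sit at its nearest end).
* **Tissue collection**: three datasets whose per-dataset case/control
  sizes default to (8, 8, 9) vs (9, 9, 8) — 25 cases and 26 controls in
  total, the scale of the emulated glomerular collection. Each dataset
  has its own probe universe (1 + Poisson(1) probes per gene, i.e. mean
  multiplicity 2), per-gene platform offsets ~ N(0, 0.5²) drawn once per
  dataset (making cross-platform combination non-trivial without explicit
  batch modeling), probe offsets ~ N(0, 0.3²) and probe noise σ = 0.3 on
  top of the gene signal. The 100 planted DE genes shift by 2 σ in cases.
  Power analyses and the end-to-end recovery checks use 13 v 13 per
  dataset, the canonical balanced configuration at which a 2 σ effect
  yields per-dataset z ≈ 4 and combined Z comfortably beyond 5.
* **Overlap study**: 30 genes planted in both cohorts with consistent
  positive direction (the up/up signature the default pipeline mode
  recovers); remaining signal genes are disjoint between cohorts with
  random signs.

Gaussian noise on the log2 scale is used throughout: the pipeline's tests
are rank- and t-based, so Gaussian data suffices for calibration and
recovery claims. Trend genes shift linearly per stage step — the monotone
alternative the JT test targets — since no dose–response shape is
specified by the emulated study. What the generator does **not** emulate:
raw two-color scanner artifacts (the M/A fixtures for normalization tests
are constructed directly), heavy-tailed or heteroscedastic noise,
correlated gene modules, missing-data patterns, or clinical covariates.
Passing tests therefore demonstrate correctness and calibration of the
statistics under clean conditions, not robustness to every pathology of
real microarray data. Effect sizes (δ = 0.5 σ/step, 2 σ case/control) are
calibration choices giving high but not saturated power at the study's
sample sizes; the emulated study publishes no effect-size estimates.

## 6. Numerical choices and problem sizes

* Hypergeometric tails and the weighted-Z denominator are computed in log
  space / stable closed form; p-values from `pnorm`/`pt` are clamped away
  from exact 0 and 1 before quantile transforms so no Z is infinite.
* Monte-Carlo p-values use the add-one estimator; exact enumeration
  preallocates and refuses beyond 10⁶ assignments.
* Determinism: every stochastic function takes an explicit seed;
  generators re-seed from a design-recorded seed, and sub-seeds derived
  from a master seed stay below 2³¹.
* Calibration checks in the test suite use 10,000 genes (type-I error
  bands of ±0.01 around α = 0.05 correspond to ~4.4 binomial SDs, so the
  checks are tight but stable); the end-to-end recovery study uses 5,000
  genes × 20 seeds; enumeration-oracle checks use 500 random small
  datasets with N ≤ 8. These sizes give sub-binomial-noise resolution on
  every claim while keeping the full suite in the low minutes on one CPU.

## 7. Known limitations

* The JT asymptotic method is used gene-wise in the screen; for very
  small cohorts or heavy ties the auto mode falls back to Monte Carlo,
  but the screen does not currently mix methods per gene beyond that
  rule.
* Best-probe collapse biases per-gene |Z| upward by construction; it is
  the field's convention for reannotated platforms, but `median_z` is
  provided and recommended when probe quality is uniform.
* The meta-analysis is a Z-combination, not an effect-size model: no
  heterogeneity statistics, no random effects.
* The overlap universe is the intersection of testable universes; if the
  cohorts' platforms measure very different gene sets the universe
  shrinks and the hypergeometric test loses resolution.
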