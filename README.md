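# trendmeta

Two-cohort transcriptomic discovery for staged disease: ordered-trend
screening of blood expression, weighted-Z meta-analysis of heterogeneous
case/control tissue datasets, and hypergeometric scoring of the
cross-cohort overlap.

## The scientific problem

In progressive diseases such as diabetic kidney disease (DKD), two kinds of
transcriptomic evidence are commonly available but rarely integrated:

1. **A staged blood cohort.** PBMC expression sampled across an ordered
   clinical severity scale — here healthy controls (HC), then diabetes with
   normo- (D1), micro- (D2) and macroalbuminuria (D3), then end-stage renal
   disease (ESRD). The question per gene is whether expression shifts
   *monotonically* with severity. `trendmeta` tests this with the
   Jonckheere–Terpstra (JT) statistic

   J = Σ_{i<j} Σ_{x∈group i, y∈group j} [ 1(x<y) + ½·1(x=y) ],

   a sum of pairwise Mann–Whitney counts over ordered group pairs, with
   E[J] = (N² − Σnᵢ²)/4 and the tie-corrected permutation variance.
   Exact enumeration, Monte-Carlo permutation (add-one estimator) and the
   normal approximation are all implemented and cross-checked.

2. **A collection of public case/control tissue datasets** on different
   microarray platforms with different probe universes. Following the
   eGWAS approach, each dataset yields per-probe signed Z-scores from a
   one-tailed Welch t-test (z = Φ⁻¹(1 − p₊), so case > control gives
   z > 0), probes are collapsed to genes (best-probe |z|), and genes are
   combined across datasets by the weighted Z-method

   Z_meta = Σ wᵢ zᵢ / √(Σ wᵢ²),  wᵢ = √nᵢ,

   with |Z_meta| > 5 as the genome-wide significance call.

The two screens are then intersected inside the universe of genes testable
in both cohorts, and the overlap size k is scored with the upper-tail
hypergeometric probability. Over-representation analysis against GMT gene
sets (hypergeometric + Benjamini–Hochberg, FDR ≤ 0.05) annotates the
result. Supporting steps — within-array loess and between-array intensity
quantile ("aquantile") normalization for two-color arrays, PCA outlier
flagging, one-way ANOVA gene filtering, hierarchical clustering — are
included, as is a synthetic-data generator that plants recoverable trend,
differential-expression and shared-overlap signals so that every stage is
testable without any external download.

## Worked example

Simulate a full two-cohort study with 25 genes planted as increasing in
blood *and* up-regulated in all three tissue datasets, then run the whole
pipeline:

```r
library(trendmeta)
design <- simulation_design(n_genes = 2000, n_trend_genes = 40, n_de_genes = 60,
                            n_overlap_genes = 25, n_case = 13, n_control = 13,
                            seed = 42)
study <- simulate_overlap_study(design)
pipe  <- run_overlap_pipeline(study$pbmc, study$glomerular$datasets)
pipe$overlap
#> Cross-cohort overlap: k = 25 of |blood| = 130, |tissue| = 38, N = 2000
#>   hypergeometric p = 5.662e-22
sum(study$truth$overlap_genes %in% pipe$overlap$intersection)
#> [1] 25
head(pipe$overlap$records, 3)
#>     gene   p_trend    p_meta z_meta
#> 1 G00634 1.479e-07 3.231e-13  7.190
#> 2 G00899 5.131e-07 3.135e-14  7.502
#> 3 G00601 5.131e-07 5.269e-10  6.101
```

The blood screen called 130 genes up and 91 down at p < 0.05 (about 40
planted + the expected ~5% null leakage per direction); the meta-analysis
called 38 up and 22 down at |Z| > 5 (essentially only planted genes — the
null expectation at this threshold is ~0.006 genes in 2000); all 25 planted
overlap genes were recovered, and an overlap of k = 25 in a universe of
2000 is astronomically unlikely by chance (p ≈ 6e-22). Records are ranked
by trend p, ties broken by meta p.

The JT machinery is also usable directly:

```r
g <- factor(rep(c("D1","D2","D3"), each = 2), levels = c("D1","D2","D3"),
            ordered = TRUE)
jt_test(c(1,2,3,4,5,6), g, "increasing", method = "exact")
#> Jonckheere-Terpstra trend test (exact, increasing)
#>   groups n = 2/2/2; J = 12.0, E[J] = 6.00, Var[J] = 6.3333
#>   z = 2.3842, p = 0.01111
```

A perfectly ordered arrangement attains the maximal J = 12; exactly 1 of
the 90 equally likely assignments does, so the exact one-sided p is 1/90.

## Command line

`exec/trendmeta` wraps the package functions as subcommands
(`simulate`, `normalize`, `qc`, `trend`, `egwas`, `overlap`, `enrich`,
`report`) with shared `--config`, `--seed`, `--out-dir` flags; every run
writes a `run_log.json` with the resolved configuration, seed, input
checksums and stage record counts.

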