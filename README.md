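# lpsprs

Can ultra-low-coverage whole-genome sequencing (0.5-2x) replace a
genotyping array for polygenic risk scoring? `lpsprs` is an R package
that builds the full evaluation loop for this question on synthetic
data, for statistical geneticists and methods developers who want the
moving parts of the low-pass-sequencing argument — genotype likelihoods,
haplotype-copying imputation, allele-frequency-stratified concordance,
clumping + thresholding scores — as small, testable, seeded components.

## What is inside

At sub-1x depth most sites carry 0-2 reads, so fixed genotype calls are
unreliable. The package contrasts two imputation philosophies inside the
*same* model: a diploid Li–Stephens copying HMM over a phased reference
panel, whose hidden state is an ordered pair of panel haplotypes with
per-interval switch probability `1 − exp(−ρ·d)` and per-allele miscopy
`μ`, run by exact scaled forward–backward (compiled core). The two modes
differ only in the emission at site *m*:

* **GL mode** — the genotype-likelihood triple
  `L(g) = Binom(n_alt; n, p_g)`, `p_g = (g/2)(1−e) + (1−g/2)e`;
* **hard-call mode** — `1−θ` on the fixed call, `θ/2` elsewhere, flat at
  missing sites (the array route is this mode restricted to array
  sites).

Around the HMM sit: a panel/cohort simulator (1/p frequency spectrum,
founder-mosaic LD, panel-absent private alleles), a site-level read
model with binomial downsampling, coverage breadth and Lorenz/Gini
uniformity over 10-kb windows, a concordance suite (pooled Pearson R²,
non-reference discordance, FPR/FNR, per-AF-bin aggregate R² with the
conventional 0.5% / 5% bin edges, cross-platform "fraction more
accurate"), MaCH-style INFO scores (`r̂² = Var(DS)/2p̂(1−p̂)`, filter at
0.3), a liability-threshold case/control generator (87 cases / 101
controls by default), PRS `Σ w_k X_k` with effect-allele flipping and
mean-zero normalization, greedy LD clumping (r² ≥ 0.5 excluded) with a
P-value threshold scan (5e-2 … 1e-20), and Mann–Whitney AUC with a
stratified bootstrap CI. VCF (GT/PL/DS/GP) and TSV weight-table I/O
connect the pieces to real files.

## Worked example

Impute one low-pass cohort and score its concordance:

```r
library(lpsprs)
panel  <- simulate_panel(100, 200, maf_min = 0.01, seed = 1)
cohort <- simulate_cohort(panel, 8, seed = 2)
reads  <- simulate_reads(cohort, mean_depth = 1, seed = 3)
imp    <- impute_gl(compute_gl(reads), panel)
imp
#> Imputed dosages (gl emissions): 8 individuals x 200 sites
#>   INFO score: median 0.600, 61.5% of sites >= 0.3
concordance_report(cohort, imp, panel_af(panel),
                   sites = filter_by_info(imp, 0.3))
#> Concordance over 123 sites x 8 individuals:
#>   R2 = 0.9124, NDR = 0.1080, FPR = 0.0278, FNR = 0.0323
#>     bin   n pooled_r2   mean_r2     sd_r2 n_defined
#>    rare   0        NA        NA        NA         0
#>     low  14 0.9087873 0.9505263 0.1525992        14
#>  common 109 0.9103290 0.9088145 0.1198280       108
```

At 1x, 63% of sites have at least one read, yet after GL-mode imputation
the dosages correlate with the true genotypes at R² = 0.91 and only
~11% of alternate-allele genotypes are discordant; the INFO filter has
kept 123 of 200 sites. `coverage_profile(reads)` adds breadth and
uniformity (here 62.6% covered, Gini 0.533 over 10-kb windows).

The full case/control study — imputation at three depths plus a
simulated array, unadjusted and P+T scores, AUC and cross-platform
agreement — is one call:

```r
ex <- run_experiment(default_prs_config(seed = 1))
prs_table(ex)[, c("arm", "auc_unadjusted", "ci_low", "ci_high", "auc_pt")]
#>       arm auc_unadjusted ci_low ci_high auc_pt
#>     truth          0.602  0.518   0.688  0.615
#>     array          0.591  0.506   0.676  0.610
#>  lps_0.5x          0.574  0.490   0.662  0.594
#>    lps_1x          0.604  0.518   0.690  0.620
#>    lps_2x          0.611  0.527   0.698  0.628
ex$prs$correlations
#>  platform_a platform_b     r    r2
#>       truth      array 0.978 0.957
#>    lps_0.5x      array 0.910 0.828
#>      lps_1x      array 0.969 0.939
#>    lps_2x       array 0.978 0.956
```

Every arm discriminates cases from controls at a similar level (AUC
around 0.6 with overlapping CIs), and scores computed from 1-2x
sequencing agree with array-based scores at r ≈ 0.97 — the low-pass
route loses essentially nothing for PRS while reading the whole site
grid. `default_concordance_config()` runs the depth-grid study
(0.5/1/2/5x, both emission modes, array route) that shows *why*: GL-mode
R² stays high and flat across depths while hard-call-mode accuracy
collapses below 2x.

The methods vignette (`vignettes/lpsprs-methods.Rmd`) documents the
models, parameter choices, numerical conventions and limitations.

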