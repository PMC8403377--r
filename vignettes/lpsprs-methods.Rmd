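---
title: "Low-pass sequencing, imputation and polygenic scores: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-pass sequencing, imputation and polygenic scores: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question this package studies

Low-pass whole-genome sequencing (LPS, roughly 0.5-5x mean depth) is a
cheap alternative to genotyping arrays for cohort studies. At such depths
most sites carry zero, one or two reads, so fixed genotype calls are
unreliable; the established remedy is to keep the full genotype-likelihood
triple per site and let a haplotype-copying imputation model resolve the
uncertainty against a phased reference panel. `lpsprs` builds the entire
evaluation loop for this design question on synthetic data: simulate a
panel and a target cohort, generate read evidence at a chosen depth,
impute with the *same* hidden Markov model under two emission regimes
(genotype likelihoods versus fixed calls), and compare the two routes -
and a simulated genotyping array - by coverage, genotype concordance, and
downstream polygenic risk score (PRS) behaviour in a case/control cohort.

Everything is seeded and pure: every simulation is a deterministic
function of its arguments.

## The copying model

### Reference panel and targets

`simulate_panel()` draws per-site alternate-allele frequencies from a
density proportional to $1/p$ truncated to $[\mathrm{maf_{min}}, 0.5]$,
the classical neutral-spectrum shape that guarantees the rare
(AF < 0.5%), low (0.5-5%) and common (>= 5%) strata are all populated.
Twenty founder haplotypes carry independent Bernoulli alleles; the
remaining panel haplotypes are founder mosaics (switch intensity 5e-6/bp),
which induces realistic linkage disequilibrium. When a minimum MAF is
requested it is enforced by injecting carriers at random haplotypes, and
that injection is precisely what creates the rare tail: a 250-haplotype
panel can represent frequencies down to 0.4%.

`simulate_cohort()` generates each target haplotype by the Li-Stephens
copying process over the panel: switch probability
$1 - e^{-\rho\,d}$ per interval of length $d$, uniform switch
destination, and a per-allele flip probability $\mu_{mut}$
(`mutation_rate`). Two defaults matter and were chosen once, for stated
reasons:

* `switch_rate` $\rho = 10^{-6}$/bp - one expected switch per 1-Mb
  region. This places the targets firmly inside the model class of the
  imputation HMM and reproduces the regime reported for real
  population-specific panels, where the disease-associated SNPs used for
  PRS are imputed almost perfectly from ultra-low coverage. With much
  weaker LD the synthetic imputation would be uniformly poor at every
  depth, which is not the system under study.
* `mutation_rate` $= 2\times10^{-3}$ per copied allele. This models
  private variation absent from the reference panel. It is the mechanism
  that makes the allele-frequency-stratified contrast meaningful: at a
  rare site roughly a third of cohort carriers hold a panel-absent allele
  that *no* amount of LD tagging can recover - only direct sequencing
  reads can see it. Arrays lose exactly there, which is the structural
  reason low-pass sequencing outperforms arrays at rare frequencies.

### Read evidence

`simulate_reads()` is site-level: depth per (individual, site) is
Poisson at the requested mean (negative binomial when overdispersion is
requested, inflating the variance for the coverage-uniformity analysis),
and each read is alternate with probability $(g/2)(1-e) + (1-g/2)e$. The
default base error $e = 0.002$ corresponds to modern short-read qualities
after filtering (about Q27); genotype likelihoods are the binomial
$L(g) = \Pr(n_{alt} \mid n, p_g)$ stored in log space. Read lengths,
mapping qualities and indels are deliberately out of scope - every metric
in the pipeline consumes per-site evidence only. `downsample_reads()`
thins each read independently (binomial thinning), the standard model of
proportional subsampling of a high-coverage run; thinning a Poisson depth
is again Poisson, and sequential thinning composes.

### The imputation HMM

The computational core (`impute_gl()`, `impute_hardcall()`) is a diploid
Li-Stephens HMM: the hidden state is an *ordered pair* of panel
haplotypes (size $K^2$, no collapsing), transitions act independently on
the two haplotypes with uniform switch destination, and a per-allele
miscopy rate $\mu$ (default $1/K$) smooths the emission. The two modes
differ only in the per-site likelihood triple:

* GL mode: the observed genotype likelihoods;
* hard-call mode: $1-\theta$ on the called genotype, $\theta/2$
  elsewhere ($\theta$ = `call_error`, default 0.01), flat at
  missing/untyped sites.

This isolates the entire contrast between the two imputation philosophies
in the emission model, with identical priors and machinery. The array
route is hard-call mode applied to calls available only at array sites.

We compute the exact posterior by scaled forward-backward rather than the
Gibbs sampling used by production GL-imputation tools: at desk scale
(panel of a few hundred haplotypes, a few hundred sites) the exact
posterior is what a sampler approximates, so it is the cleaner referent.
This is a methodological stand-in, not a reimplementation of any tool.
The $K^2 \to K^2$ transition sum collapses to row/column sums, the
recursion is scaled per site (with the scaling constants folded into the
next step's coefficients), and the hot loops live in compiled code. There
is no chunking/ligation machinery - a single region at this scale does
not need it.

Posterior genotype probabilities, dosages $DS = GP_1 + 2\,GP_2$, and the
MaCH-style INFO score $\hat r^2 = \widehat{Var}(DS) / (2\hat p(1-\hat p))$
(population variance; 0 at monomorphic dosage; clipped to $[0,1]$) come
out per site. Sites with INFO strictly below 0.3 are filtered by default
in both modes; production pipelines state this filter only for the
hard-call route, so `filter_by_info()` exposes the threshold.

## Metrics

* Coverage: fraction of sites with depth >= 1, and the Gini coefficient
  of the Lorenz curve of per-10-kb-window read counts (trapezoidal area;
  empty windows included - excluding them would understate nonuniformity
  at very low depth). Equal counts give 0; concentration approaches 1.
* Concordance: pooled Pearson $R^2$ between true genotypes and dosages;
  non-reference discordance rate (NDR) on best-guess genotypes (argmax
  GP, ties toward the smaller genotype); FPR (truth hom-ref, imputed
  carries an alternate) and FNR (truth carries an alternate, imputed
  hom-ref).
* AF-stratified aggregate $R^2$: reported **both** pooled within each bin
  and as mean +/- SD of per-SNP $R^2$, with explicit labels - the term
  "aggregate R2" conventionally means the pooled quantity, but a reported
  SD implies the per-SNP distribution, so both are emitted.
* Cross-platform comparison: restricted to the intersection of
  INFO-retained sites on both platforms. This matters: each platform's own
  retained set drops exactly the sites where that platform failed, so
  platform-specific filtering biases any direct comparison.
* Undefined results (constant truth, empty denominators, no qualifying
  SNPs) are `NA`, never 0.

## PRS and discrimination

`assign_effects()` plants `n_causal` (default 16) causal SNPs with
standard-normal effects rescaled so the standardized genetic score has
variance $h^2$ (default 0.05 - together with 1% prevalence this puts the
truth-genotype AUC in the low-0.6s, the reported range for Parkinson's
disease PRS in East Asian cohorts). Causal SNPs are drawn from the common
stratum (MAF >= 5%) by default, matching the observation that
GWAS-significant risk SNPs for complex disease are overwhelmingly common.
Published weights are the true effects plus Gaussian noise; causal
P-values come from a Wald normal approximation at an effective GWAS
sample size of 30,000 (the real effective size behind any given weight
table is unknowable, so this is a free, documented parameter), non-causal
P-values are uniform.

`simulate_phenotypes()` is the liability-threshold model: liability =
standardized-genotype score + $N(0, 1-h^2)$, case iff liability exceeds
$\Phi^{-1}(1-K)$ at prevalence $K$, then 87 cases and 101 controls are
sampled from a 20,000-strong pool.

`compute_prs()` is the weighted effect-allele count
$\mathrm{PRS}_i = \sum_k w_k X_{ik}$ with the dosage flipped to $2 - DS$
when the effect allele is the reference allele; dosages (not best-guess
calls) are scored for imputed data, and scores are normalized to mean
zero. Missing SNPs are skipped and logged (mean-imputation of missing
entries is available but off the default path). `ld_clump()` is greedy by
ascending P-value, excluding any SNP whose squared genotype correlation
with a kept SNP reaches 0.5; `p_plus_t()` clumps once, scans P-value
thresholds from 5e-2 down to 1e-20, and returns the best-AUC threshold
(ties resolve to the most inclusive threshold) together with the full
table.

AUC is the midrank Mann-Whitney statistic; its 95% interval is a seeded
stratified bootstrap (2,000 resamples) - simple, distribution-free, and
easy to verify by simulation, since no particular interval method is
canonical here. The ROC is the exact step function over unique
thresholds.

## The experiment driver and its two presets

`run_experiment()` runs, from one config: panel -> cohort -> 27.2x reads
-> thinning over the depth grid -> GL-mode and hard-call-mode imputation
plus the array route -> INFO filter -> coverage + concordance (+
AF-stratified and cross-platform tables), and optionally the case/control
PRS study (unadjusted score on the genome-wide-significant clumped set,
P+T, AUC, per-group score distributions, cross-platform score
correlations). One global seed fans out as `seed * 100 + stage offset`.
Mirroring the two cohorts of the motivating study design, two presets are
provided rather than one monolithic run:

* `default_concordance_config()` - 8 deeply sequenced individuals,
  250-haplotype panel over 500 sites of a 1-Mb region (the rare bin needs
  panel frequencies below 0.5%, hence K > 200), depth grid
  {0.5, 1, 2, 5}x. About half a minute on one CPU.
* `default_prs_config()` - 87 cases / 101 controls from a 20,000 pool,
  100-haplotype panel over 400 sites, arms {array, 0.5x, 1x, 2x} plus the
  truth genotypes. About 20 seconds.

These problem sizes are the package's desk-scale choices: large enough
that every frequency stratum and every arm is populated, small enough
that the full default grid and the test suite run comfortably on a
laptop. The acceptance checks run the concordance preset at 5 seeds, and
an AF-stratified variant with 32 individuals (8 individuals give only a
couple of rare-bin carriers per replicate, far too few for a stable
pooled $R^2$).

## What the synthetic data does and does not show

The generator reproduces the *structure* of the real design: a rare-heavy
frequency spectrum, LD from haplotype copying, panel-absent private
alleles, depth-dependent read sparsity, array ascertainment bias toward
common variants, and a liability-threshold disease with common causal
SNPs. It does not attempt coalescent realism, population structure,
indels, sex chromosomes, mappability (real coverage saturates near 86%
of the genome; the synthetic genome is fully mappable, so printed
coverage fractions approach 1 at high depth), base-quality recalibration
or genotyping-array chemistry. Passing tests therefore demonstrate that
the algorithms are correct and that the qualitative contrasts (GL beats
fixed calls at low depth; accuracy stratifies by allele frequency;
sequencing beats arrays at rare sites; platforms agree on PRS) emerge for
the stated mechanistic reasons - not that any particular real-data number
is reproduced. Real-data headline values depend on panel depth, genome
mappability and cohort ancestry, none of which are modelled.

## Numerical and design notes

* Forward-backward agreement with exhaustive path enumeration is exact to
  1e-10 on small instances; posteriors are normalized to 1e-9.
* Degenerate inputs: zero-depth likelihood triples are flat; an all-zero
  emission column resets the recursion to flat (and cannot arise from
  `compute_gl()`); Gini is undefined (error) on all-zero windows; Pearson
  $R^2$ on a constant vector, NDR with an empty qualifying set, and a
  quality-restricted comparison with an empty SNP set are `NA`.
* Hard-call and best-guess ties break toward the smaller genotype,
  deterministically.
* An INFO score exactly at the threshold is retained ("below" is strict).
* `h2 = 0` is accepted (all causal effects zero) so the null calibration
  experiment - chance-level AUC under zero heritability - is expressible.
* Configs serialize to JSON at 17 significant digits and round-trip
  bit-exactly; reports written twice from the same config are
  byte-identical.
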