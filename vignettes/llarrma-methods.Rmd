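---
title: "Resample model averaging with local LASSO regularization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resample model averaging with local LASSO regularization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A genome-wide association scan flags a *hit region*: a genomic interval
whose SNPs associate with a case-control phenotype.  Within the region,
linkage disequilibrium (LD) means many SNPs tag the same underlying
signal, and the standard single-locus analysis scores all of them
highly — a "cloud of association" in which the SNP actually carrying
the signal need not rank first.  The task this package addresses is
*reprioritization*: given the region's genotypes (possibly incomplete)
and the binary phenotype, produce one score per SNP such that the
top-ranked SNPs are enriched for true signals.

## The model and the RMIP

Let $X$ be the $n \times m$ additive-coded genotype matrix (entries
count the coded allele: 0, 1, 2, or a dosage in $[0,2]$) and
$y \in \{0,1\}^n$ the phenotype with $n_1$ cases and $n_0$ controls.
The working model is the additive multi-SNP logistic regression

$$\operatorname{logit} \Pr(y_i = 1) = \mu + \sum_{j=1}^m x_{ij}\beta_j .$$

A sparse fit of this model — the LASSO, which minimizes
$-\tfrac1n \ell(\mu, \beta) + \lambda \sum_j |\beta_j|$ with the
intercept unpenalized over the column-centered design — selects a
subset of SNPs, but a single selected model hides how sensitive the
selection is to sampling.  The package therefore scores each SNP by its
**resample model inclusion probability (RMIP)**: stratified subsamples
$k = 1, \dots, K$ are drawn without replacement
($\lceil \phi n_1 \rceil$ cases, $\lceil \phi n_0 \rceil$ controls),
the LASSO is fit within each at a subsample-specific penalty
$\hat\lambda_k$, the active sets form a $K \times m$ binary inclusion
matrix $\Gamma$, and

$$\mathrm{RMIP}_j = \frac1K \sum_{k=1}^K \Gamma_{kj} .$$

Sub-sampling (rather than bootstrapping) avoids duplicated individuals,
which would be unrealistic for genetic data; $\phi = 0.5$ is the
default and exposed as a parameter.

## Local, automatic penalty selection

The defining feature of the method is that $\lambda$ is chosen *inside
each subsample* ("local automatic regularization"), by one of two
criteria.

**Permutation selection** (default).  For a centered design the smallest
all-zeroing penalty has the closed form
$\lambda_{\max} = \tfrac1n \max_j |\langle x_j, y - \bar y \rangle|$.
Permuting the subsample's response $S$ times and taking the **median**
of the resulting $\lambda_{\max}$ values gives a penalty at which the
LASSO would select nothing about half the time were the phenotype
unrelated to the genotypes — a discovery-calibrated choice.  The median
(not the maximum) is used so that accuracy improves with $S$; $S = 25$
is the default.  The selected penalty may exceed the subsample's own
$\lambda_{\max}$, in which case that subsample contributes an empty row
to $\Gamma$ — expected behavior under weak signal, not an error.

**Complement deviance selection.**  Fit the path on the subsample, then
pick the grid penalty minimizing the binomial deviance of the
subsample's *complement* (the held-out individuals), predicting with
the subsample-fit intercept and coefficients applied to complement rows
centered by the *subsample's* column means — the frame in which the
model was fit.  Ties go to the larger (sparser) penalty.  This
criterion targets out-of-sample prediction rather than discovery and
costs roughly one full path evaluation more per subsample.

Numerical conventions: the loss is normalized by $n$, which gives
$\lambda_{\max}$ the closed form above and makes the permutation
criterion independent of the solver; the penalty grid is 100 log-spaced
values from $\lambda_{\max}$ down to $0.001\,\lambda_{\max}$; a
selected penalty is snapped to the nearest grid value with ties toward
the larger one; a coefficient is "active" when its magnitude exceeds
1e-8.  Path fitting is delegated to coordinate descent (glmnet) with
convergence threshold 1e-12 by default, at which the KKT stationarity
conditions hold to about 1e-6 at every grid point.  Replicated
simulation studies relax the threshold to 1e-8: the binary inclusion
calls stabilize several orders of magnitude before the coefficients
stop moving, and this is where the compute time goes.

## Missing genotypes

Hit-region data typically have missing genotypes.  Given per-entry
posterior probabilities over $\{0, 1, 2\}$ (from haplotype-based
imputation software, read with `read_posteriors()`, or from the
built-in `naive_posterior()` stand-in), the package supports:

* **hard** imputation — maximum a posteriori genotype, ties broken
  toward the larger expected dosage;
* **dosage** imputation — posterior-mean allele count, a fractional
  plug-in value;
* **multiple** imputation — an ensemble of complete matrices sampled
  from the posterior; subsample $k$ is drawn from the $k$-th sampled
  imputation, so the RMIPs integrate over imputation uncertainty at no
  extra fitting cost.

`naive_posterior()` conditions on the two most-correlated SNPs via a
pseudocounted joint frequency table.  It exists so the pipeline is
testable without external phasing software; it is *not* a competitor to
haplotype-based imputation and should not be preferred to it on real
data.

## Competitors

`single_locus_scores()` is the standard GWAS benchmark: each SNP alone
in a logistic regression, scored $-\log_{10} P$ from a 1-df likelihood
ratio test (capped at 300 under separation).  `stability_selection()`
is the global-penalty counterpart of the core method: one grid from the
full data's $\lambda_{\max}$, every subsample's path fit on it, and
per-grid-value selection frequencies (the "stability path").  Because
stability selection leaves its penalty free, benchmarking uses
`oracle_lambda()`: the grid penalty whose RMIPs maximize a
truth-dependent criterion (by default the initial AUC, below) — a
deliberately unfair calibration that gives the competitor its best
possible showing.  Constant RMIP rows score zero by convention; ties go
to the larger penalty.

## Evaluation

Methods are compared by their ability to discriminate the $q$ true
signal SNPs from the $m - q$ background SNPs.  For a score threshold
$t$, power is the fraction of true signals scoring $\ge t$ and the FPR
the analogous background fraction.  Sweeping $t$ over the distinct
scores (ties entering together) traces an ROC curve; the **windowed
AUC** integrates it by the trapezium rule over FPR $\in [a, b]$ with
linear interpolation at the window edges, normalized by $b - a$ so
windowed and full AUCs share a $[0,1]$ scale.  The **initial AUC**
(window $[0, 0.05]$) emphasizes enrichment among top-ranked SNPs — the
operationally relevant regime when only a few SNPs can be followed up.
The full-window AUC equals the tie-corrected Mann-Whitney statistic, a
property the tests exploit as an independent oracle.  Across replicated
trials the mean AUC is reported with variance = cross-trial sample
variance / trial count (a normal approximation); curves are aggregated
by threshold averaging (mean FPR and mean power at each threshold).

## What the synthetic data emulate

The original cancer-study and WTCCC-'58 genotypes are not
redistributable, so the package generates synthetic hit regions that
reproduce the *statistical shape* of the benchmark designs:

* **Genotypes** come from a haplotype-pool model: per LD block, a small
  pool of founder haplotypes (allele frequencies uniform on
  $[0.05, 0.95]$) from which each individual copies two haplotypes with
  a per-SNP mutation probability.  Pool size and mutation rate directly
  control within-block $r^2$; blocks are independent.  The default
  layouts (`blocks_region183()`, `blocks_region500()`) match the two
  benchmark regions' SNP counts (183 and 500) and their described LD
  character — moderate LD for the 183-SNP region, many blocks of strong
  LD mixed with weaker ones for the 500-SNP region.  This model is
  deliberately simple (no coalescent genealogy, no LD decay with
  distance within a block, no allele-frequency spectrum matching); it
  gives seedable, controllable LD, which is what the method's behavior
  depends on.  Passing tests on these data show the machinery is
  correct under controlled LD, not that performance numbers transfer to
  any particular real region.
* **Causal placement**: the five-signal design places two confounded
  pairs (within-pair $r^2$ constrained to $[0.3, 0.9]$ by default —
  correlated enough to confound, distinguishable in principle) in the
  first two blocks plus one free signal in the third; the
  variable-$q$ design places $q$ signals uniformly.
* **Effects**: the moderate set is a random permutation of five odds
  ratios spanning 1.246-1.419 (interior values log-evenly spaced — a
  reconstruction; only the endpoints are authoritative).  Small effects
  are signed draws with $|\log \mathrm{OR}|$ normal around
  $\log 1.25$ (sd $0.05 \log 1.25$, truncated positive), matching
  "odds ratios around 1.25" in either direction.
* **Phenotypes**: Bernoulli draws from the logistic model with causal
  columns centered and the intercept solved by bisection so the
  *expected* case fraction is exactly one half.
* **Missingness**: per-SNP raw proportions from a two-component uniform
  density (80% of SNPs low, 20% up to $4 p_{total}$ — missingness
  "varies considerably from SNP to SNP"), a random 90% of individuals
  eligible (so at least 10% stay complete), and a global rescaling so
  the realized missing fraction hits the target $p_{total} = 0.10$ up
  to rounding.

## Design choices where the design was open

* The genotype coding polarity (risk vs reference allele) does not
  affect RMIPs — the LASSO is sign-symmetric and single-locus scores are
  polarity-invariant — so the coding is fixed to the count of the VCF
  ALT (or PLINK counted) allele with no minor-allele re-polarization.
* Subsample sizes round up, guaranteeing both classes are represented
  for any valid $\phi$.
* Per-subsample RNG streams are derived from one master seed by a
  counter scheme (`subsample_seed()`), so growing $K$ never reshuffles
  earlier subsamples and every fit is exactly reproducible; the
  per-subsample order of operations (draw, then criterion) is part of
  the public contract and is verified in the tests by a hand-composed
  loop.
* In permutation mode the path is fit only down to the snapped target
  penalty: warm-started coordinate descent solutions at a grid point do
  not depend on later (smaller) penalties, so this is exact, and it is
  why permutation selection is several times faster than complement
  deviance — consistent with the large timing gap between the two
  criteria reported for the original implementation.
* Complement predictions clamp fitted probabilities to
  $[10^{-12}, 1 - 10^{-12}]$ so a saturated wrong prediction yields a
  large finite deviance rather than an infinite one (which would make
  ties among penalties meaningless).
* The variance attached to a mean AUC uses the sample variance (n-1
  denominator) divided by the trial count.

## Problem sizes used by the shipped studies

The replicated method comparison in the test suite (the orderings of
mean initial AUCs across LLARRMA, single-locus regression and oracle
stability selection) runs the five-signal variable-$q$ design at
$n = 2199$ on a 250-SNP panel obtained by truncating the
`blocks_region500()` layout (`reduce_blocks()`), with $K = 50$
subsamples, $S = 25$ permutations, 50 replicates, and the solver at
threshold 1e-8.  These sizes are the package's own benchmark choice:
they preserve the benchmark's sample size (and hence per-SNP power) and
its LD character while keeping a full three-method, 50-replicate
comparison at single-machine scale.  Two caveats on interpreting that
comparison.  First, the relative orderings depend on the panel size:
with fewer background SNPs the single-locus ranking faces fewer chances
to be outranked by correlated background, so shrinking the panel
flatters it.  Second, the oracle calibration of stability selection is
advantageous by construction — it picks, per trial, the stability-path
row that maximizes the criterion against the known truth — and on
exchangeable-block synthetic LD it finds ultra-sparse, nearly pure rows
more readily than decaying real-data LD would allow.  Orderings
measured on this generator at a reduced panel are therefore a harsher
test for the locally regularized method than the real-data benchmark.
Calibration checks (expected 50/50 case split; missingness targets) run
at the full printed design sizes ($1493-1500 \times 183$).

## Known limitations

* The haplotype-pool generator has exchangeable SNPs within a block: no
  LD decay with distance, and the marginally strongest SNP in a block
  is more often the causal one than in real haplotype data.  Relative
  method performance measured on it can therefore differ from real
  hit regions, particularly for comparisons that hinge on fine LD
  structure.
* Only additive coding is supported; dominance or epistatic effects and
  grouped (e.g. haplotype-level) penalties are out of scope.
* The tool analyzes one pre-identified hit region; it is not a
  genome-wide scanner, and it never fits phasing/imputation models
  itself — it only consumes their output.
* Single-locus scores cap at $\log_{10} P = 300$ under separation; SNPs
  at the cap tie.
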