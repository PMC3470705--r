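# llarrma

Reprioritizing SNPs inside a GWAS hit region under strong linkage
disequilibrium (LD), by resample model averaging of L1-penalized
logistic regressions with a **locally, automatically chosen penalty**.

## The problem and the method

After a genome-wide scan flags a hit region, single-locus tests score
every SNP correlated with the causal variants, so the top of the
marginal ranking is a cloud of LD proxies.  This package scores each
SNP by its **resample model inclusion probability (RMIP)**: draw K
stratified case-control subsamples without replacement (proportion phi
of each class), fit the additive multi-SNP LASSO logistic model

    minimize  -(1/n) loglik(mu, beta) + lambda * sum_j |beta_j|

within each subsample on the column-centered genotypes (intercept mu
unpenalized), record which SNPs are active, and average:

    RMIP_j = (1/K) * sum_k Gamma[k, j]

The penalty is chosen *inside each subsample* (locally), either by
**permutation selection** — the median over S response permutations of
the smallest all-zeroing penalty

    lambda_max = (1/n) * max_j | <x_j, y - mean(y)> |

a penalty at which the LASSO selects nothing about half the time under
the null — or by **complement deviance selection** (the penalty
minimizing held-out binomial deviance on the subsample's complement).
Because SNPs compete for inclusion in a sparse joint model, RMIPs
concentrate on variants carrying independent signal.

Also included, exactly as needed to benchmark the method: single-locus
logistic regression (&minus;log&#8321;&#8320; P from a 1-df likelihood
ratio test), Stability Selection with an oracle-calibrated global
penalty, hard/dosage/multiple imputation from genotype posteriors,
synthetic hit-region generators (LD-block genotypes, calibrated
phenotypes, an empirical missingness algorithm), and windowed ROC/AUC
evaluation (the "initial AUC" over FPR &isin; [0, 0.05] emphasizes the
top-ranked SNPs).

## Worked example

```r
library(llarrma)

# a synthetic hit region: 500 SNPs in mixed-LD blocks, 5 small-effect
# causal SNPs (odds ratios ~1.25), expected 50/50 case-control split
set.seed(601)
dat <- sim_study2(q = 5)
fit <- llarrma(dat$genotypes, dat$y, K = 100, S = 25, seed = 601)
print(fit)
#> LLARRMA fit (perm selection)
#>   K = 100 subsamples, phi = 0.5, S = 25, seed = 601
#>   top RMIPs:
#> snp_187 snp_415 snp_468 snp_160 snp_133
#>    0.48    0.25    0.20    0.12    0.09
which(dat$truth == 1)
#> [1] 187 321 329 415 464

trial_auc(coef(fit), dat$truth, a = 0, b = 0.05)   # initial AUC
#> [1] 0.4707071
sl <- single_locus_scores(dat$genotypes, dat$y)
trial_auc(sl$score, dat$truth, a = 0, b = 0.05)
#> [1] 0.4
```

The two RMIP leaders are true signals (RMIP 0.48 and 0.25: selected in
48% and 25% of the 100 subsampled sparse fits), and on this draw the
RMIP ranking enriches the top of the list a little more than the
marginal ranking does (initial AUC 0.47 vs 0.40).  With incomplete
genotypes, pass `hard_impute()` / `dosage_impute()` output, or an
ensemble of `sample_imputation()` draws via `imputations=` for multiple
imputation.

A thin command-line front end over the same functions lives at
`inst/cli/llarrma` (`simulate`, `run`, `evaluate` subcommands).

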