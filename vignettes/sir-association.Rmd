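---
title: "Multi-phenotype association testing by sliced inverse regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-phenotype association testing by sliced inverse regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirpheno)
```

## The problem

Association studies increasingly measure many correlated traits on the same
individuals. Jointly testing q continuous phenotypes against k SNP dosages
(minor-allele counts in {0, 1, 2}) is more powerful than trait-by-trait
analysis, but classical multivariate Wald statistics pay for every extra trait
with degrees of freedom: the per-SNP statistic T1 is chi-square with q df and
the joint statistic T2 with kq df, so both lose power when q is large and a
variant affects only a subset of traits.

`sirpheno` takes the sufficient-dimension-reduction route. Under the model

$$ y_i = B^\top g_i + \varepsilon_i, \qquad
   \varepsilon_i \sim N_q(0, \Sigma), $$

the regression information that the genotype vector carries about the traits
is concentrated in a small number of linear combinations
$S_1^\top y, \dots, S_{d_0}^\top y$ (the effective dimension-reduction, or
e.d.r., directions spanning the central subspace). Sliced inverse regression
(SIR) estimates these directions from the *inverse* regression of traits on
genotypes, after which association is tested on the single reduced trait
$\tilde y_i = S_1^\top (y_i - \bar y)$ with a permutation-calibrated Wald
statistic. We follow the one-component convention ($d_0 = 1$): estimation
supports general $d_0$, but all tests operate on the first direction.

## The estimator

Given aligned matrices $Y$ (n × q) and $G$ (n × k):

1. **Standardize.** $z_i = \hat\Sigma_{yy}^{-1/2}(y_i - \bar y)$ with the
   symmetric inverse square root. We use the divisor-$n$ (maximum-likelihood)
   covariance, so that $Z^\top Z / n = I_q$ holds *exactly* in-sample. This
   choice makes the law-of-total-covariance decomposition below an identity
   rather than an approximation; every downstream statistic is invariant to
   the overall scale of $\tilde y$, so only this conservation property is
   affected by the divisor.
2. **Slice.** Partition individuals by genotype:
   * *exhaustive* — one slice per distinct observed genotype vector (at most
     $3^k$; the package refuses beyond $3^{10}$ patterns);
   * *relatedness* — for larger panels, where almost all of the $3^k$
     patterns would be empty: compute the genetic relatedness matrix (GRM,
     the empirical correlation between individuals' genotype vectors), order
     individuals along its leading eigenvector (ties broken by input order),
     cut into contiguous blocks of `target_slice_size` (default 10), and
     merge adjacent blocks left-to-right until every slice holds at least
     `min_slice_size` (default 5) individuals.
3. **Within-slice moments.** Slice proportions $\hat p_h = n_h/n$, means
   $\bar z_h$, and *centered* covariances
   $\hat v_h = n_h^{-1} \sum_{i \in I_h} (z_i - \bar z_h)(z_i - \bar z_h)^\top$.
4. **Pool.** $\hat E = \sum_h \hat p_h \hat v_h$, the sample version of
   $E[\mathrm{Cov}(z \mid g)]$. With the conventions above,
   $$ \hat E + \sum_h \hat p_h \bar z_h \bar z_h^\top = I_q $$
   exactly, so the spectrum of $\hat E$ lies in $[0, 1]$ and its small
   eigenvalues mark directions with large between-slice variation.
5. **Directions.** $\hat\eta_m$ are the eigenvectors of $\hat E$ for the
   $d_0$ smallest eigenvalues (equivalently the leading eigenvectors of the
   between-slice part $I - \hat E$); back on the trait scale
   $\hat S_m = \hat\eta_m^\top \hat\Sigma_{yy}^{-1/2}$.

On centering: one sometimes sees the within-slice second moment written
uncentered. Pooling uncentered moments returns $Z^\top Z/n = I$ for *every*
slicing, which carries no genotype information at all; centering within
slices is what realises the law of total covariance, and is what we
implement.

Numerical conventions: the inverse square root floors eigenvalues at
$10^{-10}$ times the largest and raises an error below it (a silent
pseudo-inverse would change the null distribution of the tests); eigenvector
signs are fixed by making each direction's largest-magnitude coordinate
positive, for reproducibility only — all statistics are sign-invariant.

## The tests

With $\tilde y$ in hand:

* **SIR (global).** OLS of $\tilde y$ on all k SNPs with an intercept
  ($\tilde y$ is centered; testing slopes only), then the Wald form
  $\tilde T = \hat{\tilde\beta}^\top
  [\widehat{\mathrm{Cov}}(\hat{\tilde\beta})]^{-1} \hat{\tilde\beta}$.
* **SIR-S (per SNP).** Simple regression of $\tilde y$ on each SNP
  separately, $\tilde T_j^2 = \hat\beta_j^2 / \widehat{\mathrm{Var}}(\hat\beta_j)$,
  with Bonferroni adjustment across the k SNPs for the family-wise decision.

Because $\tilde y$ is estimated *from* $G$, neither statistic is chi-square
under the null. P-values come from permutation: genotype rows are reassigned
to phenotype rows uniformly at random, and on every permuted dataset the
**entire pipeline is re-estimated** — slicing, reduction, and regression.
Freezing the reduction would break exchangeability. The implementation
exploits two invariances rather than literally re-running every step: the
slice membership of a permuted dataset is the observed assignment re-indexed
by the permutation, and the design cross-product $X^\top X$ is unchanged by
row permutation; a test verifies bit-level agreement with a naive full
recompute. P-values use the add-one estimator
$p = (1 + \#\{b: T_b \ge T_{obs}\})/(1 + B)$, so $p \ge 1/(B+1)$ and the test
is exactly valid at any B. The default is $B = 1000$ permutations;
simulation-scale runs use smaller B via `run_config()`.

Baselines: the chi-square-calibrated Wald tests `wald_T1()` / `wald_T2()`,
and three principal-component combination tests applied per SNP with
Bonferroni across SNPs — PCA1 (p-value of the first PC's regression),
PCFisher ($-2\sum_m \log p_m$ against chi-square with 2q df), and PCMinp
(Šidák-corrected minimum PC p-value). These PC tests are standard forms
chosen to match their usual one-line descriptions; per-PC tests are two-sided
t tests of the simple-regression slope.

## The synthetic-data generator

`simulate_genotypes()` draws each SNP's minor-allele frequency from
Uniform(0.3, 0.5) and genotypes from Hardy–Weinberg equilibrium
(Binomial(2, p)), independently across SNPs — i.e. common variants in
linkage equilibrium. `simulate_phenotypes()` adds $N_q(0, \Sigma)$ errors
with the AR(1) structure $\Sigma_{lm} = \rho^{|l-m|}$,
$\rho \in \{0, 0.2, 0.5, 0.7\}$ in the presets. Effect matrices for the
scenario presets (`scenario_effects()`) make only SNP 3 (effect 1.10 on the
first five traits, all-positive or alternating-sign) and SNP 4 (effect 0.02
on trait 2 only) causal. MAFs are redrawn each replicate, averaging over the
stated design.

What this emulates — and does not: independent unrelated individuals, common
variants, no LD, no covariates, Gaussian traits, homogeneous effects.
Passing tests on these data demonstrate calibration and power of the
machinery under the stated generative law; they do not speak to rare
variants, population structure, LD between test SNPs, or non-normal traits.

Default slicing in the experiment harness follows the panel size: exhaustive
for k = 5, relatedness for k ≥ 10 (at n = 1000, $3^{10}$ patterns would
leave nearly all slices empty — the motivation for relatedness slicing).

## Problem sizes and reproducibility

The package's own studies run at desk scale: 2000 null replicates with 200
permutations per test for type-I error (three binomial standard errors at
that size is ±0.015 around 0.05), 200 replicates for power, and an
n = 100{,}000 brute-force reference for direction recovery. Full-scale runs
(e.g. 100{,}000 replicates, 1000 permutations) are reachable through
`run_experiment()` arguments. Every stochastic step derives its seed from
one master seed (`run_config(seed=)`), so experiments are bit-reproducible
and independent of evaluation order; `cmd_type1()`/`cmd_power()` echo the
resolved configuration into their output tables.

## Design choices where the design was open

* **Relatedness ordering.** "Adjacent" slices need a one-dimensional
  arrangement of individuals; we order by the leading GRM eigenvector
  (computed by deterministic power iteration). Any ordering consistent with
  genetic similarity would do; this one is deterministic and cheap.
* **Merge rule.** Blocks are merged left-to-right into their right
  neighbour (the final block into its left), until all slices reach the
  minimum size — e.g. n = 13 with block size 10 collapses to a single
  13-individual slice.
* **Degenerate inputs.** A singleton slice contributes a zero covariance; a
  constant SNP is excluded from the global design and reported with p = 1
  per SNP (with a warning); an individual with a constant genotype row makes
  the GRM undefined and is an error; a rank-deficient trait covariance is an
  error advising prior dimension reduction.
* **Genotype orientation.** Counts are of the minor allele. The VCF reader
  counts alternate alleles as-is and offers `flip_to_minor = TRUE`, since
  the two conventions are not equivalent for these tests (a 0↔2 flip
  changes the slicing geometry only through re-fit).

## Limitations

Tests are specified for $d_0 = 1$; no covariate adjustment; individuals are
assumed unrelated under the permutation null (the GRM is used for slicing,
not for a relatedness-adjusted null); exhaustive slicing is capped at
$3^{10}$ patterns; the PC baselines are standard approximations, not
reimplementations of any particular reference method.

## A small worked run

```{r example, eval = FALSE}
cfg <- run_config(n_permutations = 200, seed = 42)
G <- simulate_genotypes(500, 5, seed = 1)
Y <- simulate_phenotypes(G, scenario_effects(1, 1), rho = 0.2, seed = 2)
res <- sir_tests(Y, G, cfg)
res$global
res$per_snp
```
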