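---
title: "Genomic prediction models, SNP weighting and cross-validated evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction models, SNP weighting and cross-validated evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpeval)
```

This vignette is the package's account of its methods: the statistical
models, the choices made where the design was genuinely open, the numerical
details that matter in practice, and what the synthetic-data generator does
and does not establish about real data.

## The evaluation problem

Breeding programs rank selection candidates by predicted additive genetic
merit (estimated breeding values, EBVs, or their genomic counterparts,
GEBVs). The package covers the full desk-scale workflow for a pedigreed,
partially genotyped population such as a chicken breeding line: phenotypes
measured in hatches ("batches") across generations, a multi-generation
pedigree, and a medium-density SNP panel on the recent generations.

## Corrected phenotypes

All genomic predictors use the corrected phenotype
$y_c = \hat a + \hat e$ as response, obtained from the pedigree animal
model

$$ y = Xb + \gamma W + Za + e, \qquad a \sim N(0, A\sigma^2_a),\;
   e \sim N(0, I\sigma^2_e), $$

where $X$ carries batch fixed effects, $W$ numeric covariates (typically
the first three genotype principal components), and $A$ is the numerator
relationship matrix from the tabular recursion. Subtracting the estimated
fixed part rather than refitting fixed effects in every genomic model
avoids double counting of family information and makes the downstream
models intercept-only. Because every record satisfies
$y = X\hat b + \hat\gamma W + \hat a + \hat e$ exactly, $y_c$ is literally the
record minus the estimated fixed part; with an intercept-only model it is
$y - \hat\mu$, and adding a constant to all records leaves it unchanged.

## Relationship matrices

* **A** — tabular method; diagonal $1 + F_i$; unknown parents contribute
  zero. Dense algebra throughout: at $n \le 5{,}000$ the dense build and
  Cholesky inversion are fast, and every matrix remains oracle-checkable
  against explicit formulas (sparse Henderson rules, metafounders and APY
  are out of scope).
* **G** — VanRaden form $G = Z D Z' / \sum_i 2p_i(1-p_i)$ with $Z$ the
  dosage matrix centered by $2p_i$ and $D$ diagonal SNP weights. $p_i$ is
  the *counted-allele* frequency, not folded to the minor allele: the
  centering requires the frequency of the allele that the dosage counts,
  and the two coincide only up to reflection. This is the one place we
  deliberately read "minor allele frequency" as counted-allele frequency;
  weights and the denominator use $2p(1-p)$, which is reflection-invariant,
  so nothing else is affected.
* **G$_w$** — $0.95\,G + 0.05\,A_{22}$, guaranteeing invertibility of the
  genomic block in the single-step model. For plain GBLUP, where no $A$ is
  involved, the same recipe blends toward the identity; this mirrors the
  default of the established evaluation software family.
* **H$^{-1}$** — $A^{-1} + \begin{bmatrix} 0&0 \\ 0& G_w^{-1} -
  A_{22}^{-1}\end{bmatrix}$ on the genotyped block. `ssgblup()` reorders
  internally so the genotyped animals form a contiguous trailing block.
  When $G_w = A_{22}$ the correction vanishes and single-step predictions
  equal pedigree BLUP — a degenerate limit the tests assert at $10^{-8}$.

## Variance components and the mixed-model equations

`em_reml()` implements EM-REML for the single-random-effect model with
relative tolerance $10^{-6}$ and a 200-iteration cap. The expected
quadratic-form updates are evaluated in the eigenbasis of $K$, so one
symmetric eigendecomposition is paid per call and each iteration is
$O(np^2)$. EM converges monotonically but slowly near the boundary; a
non-converged fit is returned with `converged = FALSE` rather than raised
as an error, because in CV loops a near-converged pair of components is
still a perfectly usable shrinkage ratio. Two degenerate inputs are
handled explicitly: a constant response returns both components as zero,
and $K \propto I$ sets an `aliased` flag since $\sigma^2_g$ and
$\sigma^2_e$ are then not separable.

`solve_mme()` solves Henderson's equations with
$\lambda = \sigma^2_e/\sigma^2_g$ and returns BLUPs for *all* individuals
in $K$, including those without records. It accepts either $K$ (inverted
by Cholesky with a one-shot jitter fallback of
$10^{-8}\,\overline{\mathrm{diag}}$) or a precomputed inverse such as
$H^{-1}$. The closed-form GLS/BLUP expressions are the test oracle at
$10^{-8}$.

## wssGWAS weighting

The weighting loop runs: D = I → ssGBLUP GEBVs → backsolve to marker
effects → square into variance weights $d_i = \hat u_i^2\,2p_i(1-p_i)$ →
trace-normalize to $\mathrm{tr}(D)=M$ → rebuild the weighted G → repeat
(two iterations by default, the standard recommendation). Two details are
worth recording:

* **Backsolve scale.** We use $\hat u = D Z' (Z D Z')^{-1} \hat a_g$, the
  scale at which $Z\hat u$ reproduces $\hat a_g$ (up to the mean, which the
  column-centered $Z$ annihilates). Printed versions of this recipe differ
  in where the normalizer $\sum 2p(1-p)$ sits; the choice is immaterial
  for the *weights* — the squaring step and the trace normalization cancel
  any constant factor — but only this scale satisfies the backsolve
  identity, so it is the one implemented.
* **Loop target.** The procedure is restarted at the full ssGBLUP refit
  each iteration (rather than only re-backsolving), the stronger and
  better-defined variant.

Per-window variance shares are `var(Z_w u_w)/var(Z u)` over non-overlapping
20-SNP windows; shares are nonnegative but do not sum to one because window
contributions covary.

In cross-validation the weights are learned inside each training fold by
default (`weights_source = "fold"`), which is the leakage-free protocol.
`weights_source = "full"` learns them once on all data — the situation in
which weights come from a prior full-data association study; it is faster
and mirrors that common practice, but its CV accuracies are optimistic for
the weighted model, visibly so on oligogenic traits. Both modes are
first-class; reports should state which was used.

## Machine-learning predictors

KRR is implemented natively so its algebra stays test-addressable:
$\hat y(x) = k'(K+\lambda I)^{-1}(y-\bar y)+\bar y$ with a linear or RBF
Gram matrix on raw 0/1/2 dosages (no standardization — the dosage coding
is the feature scale). With a linear kernel and matched shrinkage it
coincides with SNP-BLUP and GBLUP, a three-way identity the tests verify
at $10^{-6}$. SVR delegates to `e1071::svm` (ε-insensitive loss; an
all-inside-tube optimum yields a flat prediction at the training mean) and
random forest to `ranger` (prediction = mean of per-tree predictions;
sklearn's `min_samples_split` maps to `min.node.size`, the closest
control). Grid search is exhaustive over candidate rows, scored by mean
Pearson correlation in an internal five-fold CV, with deterministic
first-row tie-breaking; the default grids bracket the reported optima
(KRR: RBF, λ = 0.1, γ = 10⁻⁴; SVR: C ∈ {0.1, 1}, γ = 10⁻⁴; RF: 200
trees, depth 10, min split 5).

## Marker QC, LD pruning, PCs

QC applies five rules in a fixed, documented order — SNP call rate < 0.98,
MAF strictly < 0.05, Hardy–Weinberg exact test P < 10⁻⁶
(Wigginton-style two-sided exact test, the common default), individual
call rate < 0.95, unplaced-chromosome label `"0"` — each computed on the
data as it stood when the rule ran, so rerunning QC on its own output
removes nothing. Missing dosages are mean-imputed per marker *after* QC,
before G, pruning, PCA and ML features.

LD pruning follows `--indep-pairwise 50 5` semantics: a 50-SNP window
slides by 5; any retained pair with $r^2$ above the threshold loses its
lower-MAF member (ties: the later map position — the upstream tool's
internal rule is not published, so a deterministic one is fixed here).
Pruning is genome-wide in map order, and the retained count is monotone in
the threshold. PCs come from the SVD of centered, standardized dosages.

## The synthetic-data generator

The generator is the package's study population. Founder haplotypes are
mosaics of a small ancestral pool (geometric segment lengths), which
induces short-range LD that decays with genetic distance — enough realism
for pruning and weighting tests without a coalescent simulator. Offspring
are produced by gene dropping with Poisson crossovers, so Mendelian
consistency holds by construction. Traits are additive:
`y = mean + batch + Σ dosage·effect + e`, polygenic or oligogenic
(`n_qtl` markers carrying a set share of genetic variance).

Marker effects are drawn Normal and then rescaled so the *realized* sample
variance of the true breeding values equals $h^2\,\mathrm{SD}^2$ exactly.
An analytic scale from $\sum 2p_i(1-p_i)$ would only hit the target in
expectation and is biased under the LD the founder pool deliberately
creates; the empirical rescaling makes heritability calibration hold by
construction, which is what parameter-recovery tests need.

The `"wenchang"` preset emulates the reference population's scale: 735
founders plus 288×8 and 205×7 offspring (≈ 4,474 pedigree records in three
generations, ≈ 3,739 genotyped), trait presets with the reported means,
SDs and heritabilities of body weight and abdominal fat thickness at
22/32/45 weeks, and per-trait phenotype missingness matching the reported
effective record counts (culling removes records, not genotypes, so
missingness applies to phenotypes only). The number of hatches per
generation is not reported anywhere; the preset uses 5 batches with batch
SD = 0.3 × trait SD as a placeholder, and both are configurable.

What passing tests on this generator do **not** show: robustness to
genotyping error and imputation artifacts (genotypes are clean post-QC
emulations), non-additive architecture, selection and assortative mating,
or the LD spectrum of a real long-term selected line. Directional results
(e.g. weighted > unweighted on oligogenic traits) transfer as qualitative
expectations, not as effect sizes.

## Cross-validation harness

Folds partition the individuals that are genotyped *and* carry a record
for the trait — the operative population when missingness differs by
trait — into k groups whose sizes differ by at most one. Per round,
variance components are re-estimated on the training portion (a
configurable departure from re-using full-data components), the model
predicts the held-out fold, and accuracy (Pearson r against $y_c$),
dispersion bias (slope of $y_c$ on GEBV), MSE and MAE are recorded.
Corrected phenotypes themselves are computed once from the full pedigree
model, as in routine evaluations. Summaries report mean ± SE over all
rounds (not repeat means); model comparison uses one-way ANOVA with Tukey
HSD at 0.05 and compact letter groups. ssGBLUP is fitted on the raw
response with fixed effects (its H-matrix machinery expects the full
animal model; feeding it $y_c$ is also supported), and a failed model in a
round is recorded and excluded rather than aborting the run.

## Numerical choices

* Cholesky with a single jitter retry ($10^{-8}\,\overline{\mathrm{diag}}$)
  everywhere a relationship matrix is inverted; an unblended singular G
  produces an error pointing at `blend_gw()`.
* EM-REML tolerance $10^{-6}$ (relative), cap 200 iterations; residual
  variance floored at $10^{-12}\times$ the OLS residual variance.
* Grid-search ties break on grid order; LD-prune ties on map position;
  both deterministic.
* All simulation entry points derive their streams from `cfg$seed`;
  identical configs give byte-identical outputs.

## Problem sizes

The shipped tests and the acceptance script run the pipeline at reduced
scale — populations of 400–1,000 genotyped individuals and panels of
600–5,000 markers, with 2–3 repeats of 5-fold CV — sizes chosen so the
full suite exercises every code path, including fold-local wssGWAS
weighting, in minutes on a single core while remaining statistically
informative (accuracies sit well inside their theoretical ceilings, and
directional comparisons are made over 10 seeds).

## Known limitations

Single-trait models only; no dominance or epistatic components; no
genotype-by-environment terms; dense algebra bounds practical pedigrees at
a few tens of thousands; PLINK *text* dialect only (binary `.bed`, VCF and
dosage-probability formats are out of scope); the PLINK text round trip
recovers allele order only for markers observed polymorphic.
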