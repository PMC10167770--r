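---
title: "Genomic prediction of hybrid performance: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction of hybrid performance: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridGP)
```

## The problem

Hybrid breeding programs cross cytoplasmic-male-sterile seed parents
("testers") to panels of pollinator lines and field-test the resulting F1
hybrids over several environments. Synthesizing and phenotyping hundreds of
testcrosses is the costliest step of the pipeline. Genomic selection
replaces most of that phenotyping with prediction: genotype the *parents*
once, train a whole-genome regression on a subset of field-tested hybrids
(the training population, TP), and predict the genetic merit of the
untested ones (the validation population, VP) from their parents' marker
profiles alone.

hybridGP implements this workflow end to end for biallelic SNP panels on
inbred parents: marker quality control, hybrid design matrices, RR-BLUP
prediction with additive and dominance effects, multi-environment variance
components and heritability, relatedness/structure diagnostics, and the
cross-validation schemes used to judge whether prediction is accurate
enough to act on.

## Trial model, variance components and heritability

Phenotypes from a replicated multi-environment trial are modeled as

$$y_{ijk} = \mu + g_i + e_j + (ge)_{ij} + r_{k(j)} + \varepsilon_{ijk},$$

with hybrid effects $g_i$ and interactions $(ge)_{ij}$ random, and
environment $e_j$ and replicate-within-environment $r_{k(j)}$ fixed.
For balanced data `estimate_components()` solves the expected mean squares
of the genotype, genotype-by-environment and residual strata in closed
form from cell means:
$\hat\sigma^2_e = MS_{res}$,
$\hat\sigma^2_{ge} = (MS_{G\times E} - MS_{res})/r$,
$\hat\sigma^2_g = (MS_G - MS_{G\times E})/(er)$,
truncating negative solutions at zero. The closed form is exact and fast
(no factor-expanded model matrix), and `stats::aov` serves as an
independent oracle for it in the test suite. Unbalanced tables are routed
to a restricted-maximum-likelihood fit of the same model through
`lme4::lmer`. Residual variance is assumed homogeneous across
environments; heterogeneous-error fits are a known extension we do not
provide, which can shift component estimates slightly on real multi-site
data.

Broad-sense heritability of entry means is

$$H = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{ge}/e + \sigma^2_e/(er)},$$

with $e$ environments and $r$ replicates counted from the analyzed table.
$H$ is clipped to $[0,1]$ and is the standardization constant for
prediction accuracy below.

## Hybrid design matrices from parental genotypes

Parents are coded $-1/+1$ for the two homozygous classes ($0$ =
heterozygous, allowed only under the `"expected"` policy). For a cross
female $\times$ male the hybrid's expected marker states are

$$K_A = \tfrac{1}{2}(x_{fem} + x_{male}), \qquad
  K_D = \tfrac{1}{2}\,|x_{fem} - x_{male}|,$$

so parents sharing a homozygote give $K_A = \pm 1, K_D = 0$ and opposite
homozygotes give $K_A = 0, K_D = 1$ (a guaranteed heterozygote). With
fully inbred parents F1 genotypes are deterministic — no segregation —
which is what makes hybrid prediction from parental genotypes possible at
all. Both matrices are invariant to swapping the parents (no
parent-of-origin effects). Residually heterozygous parents make the cross
outcome stochastic; the `"expected"` policy records expected states
(half-integer values), while `"strict"` refuses them and is the right
setting for panels assumed inbred.

## RR-BLUP: partial and full models

The partial (additive-only) model is
$y = 1\mu + K_A a + \varepsilon$ with $a \sim N(0, \sigma^2_a I)$:
all marker effects shrunk equally under a common-variance Gaussian prior.
`fit_partial()` estimates $\lambda = \sigma^2_\varepsilon/\sigma^2_a$ by
restricted maximum likelihood using a spectral decomposition of the
additive kernel $G = K_A K_A'$, then recovers
$\hat a = K_A'(G + \lambda I)^{-1}(y - 1\hat\mu)$ with $\hat\mu$ the
generalized-least-squares intercept. Two numerical details matter:

* **Rank deficiency.** Hybrids share parents, so $K_A$'s rows span only
  the parents' space and $G$ is far from full rank. The EMMA-style
  profiling must separate the intercept's null direction from the genetic
  null directions; we add a positive offset inside the projected kernel
  before the eigendecomposition, which makes that separation exact. (An
  unmodified projection silently merges the two null spaces and REML then
  reports zero genetic variance on signal-rich data.)
* **Floors.** Variance estimates are floored at $10^{-9}$ of the
  phenotypic variance so $\lambda$ stays finite on degenerate inputs; the
  1-D search runs on $\log\lambda \in [-25, 25]$ with tolerance $10^{-8}$.

The full model adds dominance, $y = 1\mu + K_A a + K_D d + \varepsilon$
with $d \sim N(0, \sigma^2_d I)$. `fit_full()` maximizes the restricted
likelihood over the two log variance ratios by Nelder–Mead (relative
tolerance $10^{-6}$; start point: each kernel alone explaining half of
$\mathrm{var}(y)$), profiling the intercept and residual scale at each
step, then back-solves both effect vectors by BLUP. RR-BLUP in
marker-effect form and GBLUP with the corresponding kernel are the same
predictor; the test suite asserts their equivalence to $10^{-8}$ on
randomized instances, which is the strongest internal correctness check
we have for the solver.

One identifiability caveat: when hybrids are weakly related through their
male parents, the rows of $K_D$ are nearly orthogonal and $K_D K_D'$
resembles a scaled identity, so REML can trade residual variance against
dominance-kernel variance with almost no likelihood cost. Predictions and
the *realized* variance split (variances of $K_A\hat a$ and $K_D\hat d$)
are stable; the nominal $\hat\sigma^2_d$ vs $\hat\sigma^2_\varepsilon$
partition is not, and our tests therefore judge dominance recovery on the
realized scale.

Phenotypes enter the models as across-environment hybrid means
(`hybrid_means()`); environments are not modeled jointly with markers.
This matches the standard two-stage practice for balanced trials and
keeps the prediction stage a pure marker regression.

## Relatedness and structure diagnostics

`vanraden_kinship()` computes the first VanRaden genomic relationship
matrix, $K = ZZ'/(2\sum_k p_k(1-p_k))$ with $Z$ the dosage matrix centered
at twice the panel allele frequencies (no external reference panel).
`coancestry_distance()` is one minus mean identity-by-state allele
sharing — the estimator behind "co-ancestry from the SNPs directly" is not
uniquely defined in the literature, and IBS sharing is the assumption we
make. `pca_genotypes()` is an SVD of the column-centered code matrix
(unscaled), reporting percent variance explained that sums to 100 over all
components. These diagnostics exist because cross-validated accuracy is
inflated when training and validation sets contain related material;
structure should be inspected before trusting a random CV split.

## Cross-validation schemes and accuracy

Accuracy is reported as $r(\hat g, g)$: the Pearson correlation between
observed and predicted values on the validation set divided by $\sqrt{H}$,
with $H$ estimated once from the full phenotype table (not per fold).
Schemes:

* **fivefold** — random partition into five near-equal folds, each fold
  validated once per iteration; fold-level correlations are averaged
  (pooling predictions before correlating is the other convention; fold-
  level averaging is slightly conservative and is what we adopt).
* **tp_size** — random training populations of a fixed size, remainder
  validated; the workhorse for training-size response curves, summarized
  by `accuracy_gain()` (integer percent change, half-away-from-zero
  rounding).
* **common_male** — validation = all hybrids of one held-out female
  tester; training and validation then share male parents but no female.
* **common_female** — the male pollinators are partitioned and hybrids
  follow their male parent; the sides share female testers but no male.
  The published experiment this package's worked examples draw on reports
  such splits only through their sizes (136/68 and 77/127 of 204), so the
  male partition targets a training size equal to the largest tester
  group's hybrid count by seeded greedy subset-sum — an interpretation
  validated by reproducing those sizes, and stated as such.

All schemes derive every random draw from an explicit scheme seed, and
results are reproducible bit for bit given (data seed, scheme seed).

## The synthetic-data generator

`simulate_dataset()` emulates the study design the analysis assumes, so
every stage is testable without external downloads:

* **Parents.** Fully homozygous inbreds (codes $\pm 1$, no residual
  heterozygosity) in `n_subpopulations` contiguous blocks, each block with
  its own per-marker allele frequencies drawn uniformly from
  `allele_freq_range` (default $(0.1, 0.9)$) — enough divergence for
  leading-PC structure like real breeding panels show. Markers are placed
  contiguously and evenly on `n_chromosomes`.
* **Mating design.** Testers crossed to overlapping pollinator groups:
  the first `n_shared_pollinators` males enter every group, remaining
  slots are filled round-robin so every pollinator is used before any
  non-shared one serves twice. The desk-scale default is 60 pollinators,
  3 testers, groups 45/35/40 with 25 shared (120 hybrids), 2,000 markers
  on 10 chromosomes; `reference_shaped = TRUE` switches to the 99-pollinator,
  204-hybrid layout (77/59/68, 44 shared), and the full 66k-marker scale
  is reachable through `n_markers`.
* **Genetic architecture.** `n_qtl` markers (default 100) get Gaussian
  additive and dominance effects rescaled so the in-sample variances of
  the hybrids' additive and dominance values hit `var_additive` and
  `var_dominance` exactly — exact targets make heritability assertions
  testable at small n. Defaults (10 additive, 2 dominance, 4 G-by-E, 7
  residual, 4 environments, 3 replicates) give entry-mean heritability
  around 0.85, a realistic value for phenology-type traits; the source
  experiment publishes no per-trait additive/dominance split, so these
  are free simulation parameters, not estimates of any real trait.
* **Phenotypes.** One record per hybrid, environment and replicate:
  fixed environment and replicate-within-environment shifts (scales
  `env_effect_sd`, `rep_effect_sd`; set to 0 for noise-free limits),
  independent mean-zero G-by-E deviates per hybrid-environment cell, and
  i.i.d. residuals. G-by-E carries no structured correlation, matching
  the single-random-interaction trial model above.

What the generator does **not** emulate — and what passing tests on it
therefore cannot show about real data: linkage disequilibrium and
recombination-map structure (markers are exchangeable given frequencies),
epistasis, selection or drift history, spatial field trends, heterogeneous
error among environments, and unbalanced or missing field records. Real-
data accuracies depend strongly on LD between markers and causal loci and
on TP-VP relatedness; synthetic results here validate the machinery and
its qualitative behavior (accuracy rising with TP size, dominance helping
when dominance variance is real), not absolute accuracy levels.

## Reproducibility and problem sizes

Every stochastic stage draws from a named stream derived from one integer
seed (`sim_config(seed = )`, `cv_scheme(seed = )`), so identical seeds give
bit-identical genotypes, designs, phenotypes and accuracy tables. The test
suite runs desk-scale problems (tens of lines, hundreds of markers,
100-150 hybrids; 500-hybrid trials for variance-component recovery;
100-iteration CV for the training-size response), chosen so the full suite
completes in well under a minute while leaving Monte-Carlo margins that
the assertions state explicitly.

## Known limitations

* Only single crosses of two inbred parents; no three-way hybrids or
  cytoplasm effects.
* Two variance components at most in the prediction stage (additive +
  dominance); no epistatic or G-by-E-aware kernels, no Bayesian
  alternatives with marker-specific variances.
* The co-ancestry distance is an IBS proxy; pedigree-based co-ancestry
  coefficients are not computed.
* The naive modal imputer is adequate only at low missingness; use a
  haplotype-aware imputer upstream for serious missing-data settings.
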