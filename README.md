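# hybridGP

Genomic prediction of F1 hybrid performance from parental genotypes, for
testcross breeding programs in grain sorghum and similar hybrid crops.

Hybrid programs cross a few cytoplasmic-male-sterile seed parents
("testers") to large panels of pollinator lines, then field-test hundreds
of F1 testcrosses across environments — the most expensive step of hybrid
development. Because the parents are inbred, an F1's marker genotype is
fully determined by its two parents, so genome-wide marker effects trained
on a subset of field-tested hybrids (the training population, TP) can
predict the merit of untested combinations (the validation population, VP)
from parental genotypes alone. hybridGP implements that workflow: marker
QC, hybrid design matrices, RR-BLUP prediction, trial variance components,
relatedness diagnostics, and the cross-validation schemes used to decide
whether the predictions are good enough to act on.

## The model

For hybrids with additive and dominance marker states derived from their
inbred parents (per marker: parents sharing a homozygote give
`K_A = ±1, K_D = 0`; opposite homozygotes give `K_A = 0, K_D = 1`), the
package fits

- partial model: `y = 1μ + K_A a + ε`, `a ~ N(0, σ²_a I)`
- full model: `y = 1μ + K_A a + K_D d + ε`, additionally `d ~ N(0, σ²_d I)`

by restricted maximum likelihood (ridge-regression BLUP; spectral
decomposition for one kernel, derivative-free search over log variance
ratios for two). Phenotypes `y` are across-environment hybrid means.
Trial variance components come from the model
`y = μ + g + env + rep(env) + g×env + error` (genotype and interaction
random), and broad-sense heritability of entry means is
`H = σ²_g / (σ²_g + σ²_ge/e + σ²_e/(e·r))`. Prediction accuracy is
reported as `r(ĝ, g)`: the observed-vs-predicted correlation divided by
`√H`. Population structure and relatedness are profiled with VanRaden
kinship, identity-by-state distance, and genotype PCA.

A synthetic-data generator (`simulate_dataset()`) emulates the whole study
design — structured inbred panels, overlapping tester × pollinator mating
designs, QTL effects with exact variance targets, replicated
multi-environment phenotypes — so the entire pipeline is testable without
any external data. See the vignette
(`vignettes/hybrid-genomic-prediction.Rmd`) for the statistical details
and design decisions.

## Worked example

```r
library(hybridGP)

cfg <- sim_config(seed = 42)           # 120 hybrids, 2,000 SNPs, 4 env x 3 rep
sim <- simulate_dataset(cfg)

estimate_components(sim$phenotypes)
#> variance components for 'trait1' (anova): sigma2_g = 10.62,
#>   sigma2_ge = 4.871, sigma2_e = 7 (e = 4, r = 3), H = 0.855

hd  <- make_hybrid_design(sim$genotypes, sim$design)
y   <- hybrid_means(sim$phenotypes)[rownames(hd$K_A)]
fit_full(y, hd$K_A, hd$K_D)
#> gp_fit (full model): 2000 markers, mu = 51.2, sigma2_a = 0.01536,
#>   sigma2_d = 0.007655, sigma2_e = 0.02524

run_cv(sim$phenotypes, sim$genotypes, sim$design,
       cv_scheme("fivefold", iterations = 10, seed = 1), model = "partial")
#> cv_result: fivefold scheme, partial model, trait 'trait1':
#>   mean accuracy 0.800 (raw r 0.739, H = 0.855, 50 replicate(s))
```

The simulated trait recovers its target variance components (10, 4, 7)
and an entry-mean heritability of 0.86; five-fold RR-BLUP prediction
reaches a standardized accuracy of 0.80 on this mostly additive trait.
Training-size response curves (`cv_scheme("tp_size", n_tp = ...)`) and
parent-relatedness validation (`relatedness_cv()` with `common_male` /
`common_female` splits) follow the same pattern; `accuracy_gain()`
summarizes a size series as an integer percent change.

Two small published reference tables from a 204-hybrid sorghum testcross
experiment ship with the package: `sorghum_tp_accuracy()` (cross-validated
accuracies by TP size for eight traits) and `sorghum_chrom_counts()`
(retained SNPs per chromosome), used by the examples and the acceptance
script.

A thin command-line wrapper covers the same pipeline stage by stage:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/hybridgp.R", package="hybridGP"))')" \
    simulate --seed 1 --out sim_out
```

with commands `simulate`, `qc`, `kinship`, `pca`, `varcomp`, `fit` and
`crossval`, each writing its artifacts plus a checksum manifest.

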