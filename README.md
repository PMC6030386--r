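# treeglmm

Phylogeny-regularized generalized linear mixed models for predicting
clinical or biological outcomes from microbiome OTU abundance profiles.

## The problem

16S rRNA surveys summarize a microbiome sample as counts over hundreds to
thousands of OTUs related by a phylogenetic tree. Outcome-associated OTUs
are often *clustered* on that tree (related taxa share function) and often
*dense* (community-level shifts involve many weakly associated taxa).
Sparse regression methods struggle in exactly those regimes. `treeglmm`
treats the per-OTU effects **b** as random with a tree-induced correlation,
so signal is pooled across related taxa and across many weak effects.

## The model

For sample *i* with normalized abundance vector **z**ᵢ (counts / library
size) and covariates **x**ᵢ:

- continuous outcome:  yᵢ = β₀ + **x**ᵢᵀβ₁ + f(**z**ᵢ; γ)ᵀ**b** + εᵢ,
  with **b** ~ N(0, σ²_b C(ρ)) and εᵢ ~ N(0, σ²_ε);
- binary outcome:  logit E(yᵢ) = β₀ + **x**ᵢᵀβ₁ + f(**z**ᵢ; γ)ᵀ**b**.

C(ρ) is the phylogeny-induced correlation among OTU effects,
Cᵢⱼ = exp(−2ρ d²ᵢⱼ) with dᵢⱼ the patristic distance (the plain-distance
exponent is available by flag). ρ sets the phylogenetic depth of signal
grouping: ρ = 0 merges all OTUs into one effect, ρ → ∞ discards the tree.
f(z; γ) = z^γ (0 stays 0) is a power transform: small γ up-weights rare
taxa, γ = 0 reduces the data to presence/absence.

Equivalently the aggregated OTU effect is a Gaussian process over samples
with kernel K(γ, ρ) = f(Z; γ) C(ρ) f(Z; γ)ᵀ — a tree-aware microbiome
similarity. Continuous outcomes are fitted by REML through a spectral
decomposition of K; binary outcomes by penalized quasi-likelihood
(iterated weighted working LMMs). New samples are predicted by the
conditional mean, equivalently X β̂ + f(Z; γ) b̂ with b̂ the BLUP of the OTU
effects. (γ, ρ) are tuned by k-fold cross-validation (PMSE for continuous,
AUC for binary outcomes); fixing ρ = 10⁴ gives the tree-agnostic baseline.

The package also ships the full simulation framework used to validate the
method (random trees, Dirichlet-multinomial counts, phylogenetically
clustered signal clusters, non-linear signal variants, noisy trees) and a
preprocessing pipeline for real count tables (Bray-Curtis sample-outlier
filter, prevalence/median-count OTU filters, pairwise-ratio size-factor
normalization, per-taxon winsorization, square-root transform).

## Worked example

Simulate a continuous outcome driven by two large phylogenetic clusters,
tune (γ, ρ) on 100 training samples, and predict 50 held-out samples:

```r
library(treeglmm)
sim <- simulate_dataset(n = 150, p = 100,
                        design = simulation_design(m = 10, signal_density_pct = 20,
                                                   abundance_level = "high"),
                        seed = 42)
tr <- 1:100; te <- 101:150
res <- cross_validate(sim$outcome[tr], sim$proportions[tr, ], sim$dist,
                      grid = tuning_grid(n_folds = 5, seed = 42))
res
#> tuning_result (pmse over 156 cells): best gamma = 1.3, rho = 0.03125, pmse = 0.002228
res$final_model
#> treeglmm fit (gaussian): n = 100 samples, p = 100 OTUs
#> kernel_spec: rho = 0.03125, gamma = 1.3, squared distance
#> kernel LMM fit (REML): sigma_b2 = 1.248, sigma_e2 = 0.001717
#> fixed effects: -0.3887

pred <- predict(res$final_model, sim$proportions[te, ])
r_squared(sim$outcome[te], pred)
#> 0.639
```

The selected ρ = 2⁻⁵ is the smallest non-zero value on the grid — the
signal sits in deep clusters, so strong phylogenetic pooling wins — and the
held-out R² of 0.64 measures the squared correlation between predicted and
observed outcomes. Binary outcomes work the same way (`family` is chosen
automatically from a 0/1 outcome; predictions are probabilities).

A command-line interface wrapping the same functions lives at
`inst/cli/treeglmm.R` with subcommands `simulate`, `preprocess`, `fit`,
`predict`, `tune` operating on TSV/Newick/JSON files; run it with no
arguments for usage.

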