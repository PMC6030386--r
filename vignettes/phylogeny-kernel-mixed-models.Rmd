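---
title: "Phylogeny-regularized mixed models for microbiome prediction: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-regularized mixed models for microbiome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the statistical machinery it
implements: the model, the estimation algorithms, the simulation framework
used to validate them, and the numerical and design decisions taken where
more than one reasonable choice existed.

## Model

Outcomes are predicted from relative OTU abundances `Z` (samples × OTUs,
counts divided by library size), an optional covariate matrix, and a
rooted phylogenetic tree over the OTUs. Per-OTU effects `b` are random:

* continuous: `y = X beta + f(Z; gamma) b + e`, `b ~ N(0, sigma_b^2 C(rho))`,
  `e ~ N(0, sigma_e^2 I)`;
* binary: the same linear predictor through a logistic link.

`C(rho)` with entries `exp(-2 rho d_ij^2)` (patristic distances `d_ij`)
encodes the assumption that closely related taxa act alike. The model is
therefore best suited to *clustered* and *dense* signals; for sparse,
phylogenetically unrelated signals a sparse regression is the better tool,
and the tuning grid's large-`rho` fallback is what keeps the model honest
in that regime (at `rho = 1e4` the kernel degenerates to a plain linear
kernel on transformed abundances, ignoring the tree).

Key tuning parameters:

* `rho >= 0` (inverse branch-length-squared units): phylogenetic depth of
  signal grouping. `rho = 0` pools all OTUs into a single effect; large
  `rho` decorrelates them. Default search grid `{0, 2^-5, ..., 2^5}` plus
  the tree-agnostic fallback `1e4`.
* `gamma >= 0` (dimensionless): abundance weighting, `f(z) = z^gamma` with
  zeros kept at zero. `gamma = 0` is exactly the presence/absence
  indicator, matching the limit of `z^gamma` for `z > 0`. Default grid
  `{0, 0.01, 0.1, 0.3, ..., 1.9}` (steps of 0.2 after 0.1), spanning
  presence/absence through super-linear weighting.

The squared-distance exponent is the default because it groups signal more
sharply; the plain-distance exponent (`squared_distance = FALSE`) is the
variant whose positive definiteness is guaranteed by the Euclidean nature
of root-patristic distances. Distances are not rescaled by default, so
`rho` is interpretable in the tree's own branch-length units;
`rescale_distance = TRUE` divides by the median off-diagonal distance so
one grid transfers across trees of very different depths.

## Positive definiteness

With the squared exponent `C(rho)` may fail positive definiteness.
`correlation_matrix()` eigendecomposes `C`, clips eigenvalues below
`1e-10 * lambda_max` to that floor, reconstructs, and rescales to unit
diagonal, recording `pd_corrected`. The limits `rho = 0` (all ones) and
`rho = Inf` (identity) are returned exactly rather than through the
exponential and the clipping path: the all-ones matrix is PSD but rank 1,
and the floor would otherwise perturb an exact limit by ~1e-9.

## REML estimation (continuous outcomes)

The covariance of the outcome is `sigma_b^2 K + sigma_e^2 W^-1` with
`K = f(Z) C f(Z)'` and `W` optional observation weights (identity for a
plain fit). After absorbing `sqrt(W)`, `K` is eigendecomposed once and the
restricted likelihood is profiled down to one dimension — the ratio
`delta = sigma_e^2 / sigma_b^2`:

* grid: 61 log-spaced points over `delta/mean(diag(K)) in [1e-6, 1e6]`
  (anchoring to the kernel scale keeps the bracket meaningful whatever the
  units of `K`);
* refinement: `optimize()` in the bracket around the best grid point;
* boundary: the ordinary-least-squares limit (`sigma_b^2 = 0`) is always
  evaluated and wins when it dominates, reported via the `boundary` flag.

The REML criterion includes the `- log |X'X|` term, making it invariant to
the fixed-design basis; `reml_loglik_dense()` evaluates the identical
criterion by dense solves and determinants with no spectral shortcut, and
the test suite requires the two routes to agree to 1e-6 on random
instances. An intercept is always present and always first.

Degenerate inputs: a numerically zero kernel short-circuits to the
weighted least-squares fit; kernels with eigenvalues below
`-1e-8 * lambda_max` are clipped to zero with a warning.

## Prediction

New samples are predicted by the conditional mean
`X_te beta + sigma_b^2 K_te,tr Sigma_tr^-1 (y - X beta)`. Solves use a
Cholesky factorization with one jitter retry (`1e-8 * tr(Sigma)/n` added
to the diagonal): at `rho = 0` the correlation is rank one and `Sigma_tr`
can be near-singular. The equivalent BLUP form
`X_te beta + f(Z_te) b_hat`, with
`b_hat = sigma_b^2 C f(Z_tr)' Sigma_tr^-1 (y - X beta)`, is implemented as
`predict(..., form = "blup")`; the two agree to numerical precision and
the BLUP route exposes the smoothed per-OTU effects. Predictive variances
(the diagonal of the conditional covariance) are available for continuous
fits.

## Penalized quasi-likelihood (binary outcomes)

PQL iterates weighted working LMMs: from the current linear predictor
`eta`, form `mu = plogis(eta)`, weights `w = mu(1-mu)`, working response
`eta + (y - mu)/w`; fit the working LMM with residual covariance
`sigma_e^2 W^-1`; set `eta` to its fitted values. Decisions made here:

* convergence when `max |delta eta| < 1e-6`, at most 50 outer iterations;
  non-convergence is a flagged state (`converged = FALSE`), not an error;
* weights floored at 1e-6 against quasi-separation;
* `eta` capped at ±10: beyond that the fitted probabilities are
  numerically 0/1 and the working response explodes;
* adaptive damping: when the step size stops shrinking the update is
  halved (down to 1/32). PQL genuinely diverges when the kernel can
  interpolate the training labels — the mixed-model analogue of the
  infinite MLE under logistic separation, common at small `n` with
  `p > n`; damping plus the cap keeps the iteration bounded and the
  flagged fit usable for prediction;
* the working-model dispersion `sigma_e^2` is *estimated*, not fixed at 1.
  Estimating it is the more general choice; the estimate is reported so a
  user can judge how far it sits from 1.

Binary prediction applies the conditional mean to the converged working
model (working response in place of the outcome, weighted covariance) and
maps through the inverse logit. Stored working response and weights make
prediction reproducible from a serialized model without refitting.

## Cross-validated tuning

`cross_validate()` evaluates every (gamma, rho) cell by k-fold CV (default
5), minimizing held-out PMSE (continuous) or maximizing AUC (binary,
folds stratified by class), then refits the winner on all samples. Ties
break at the first optimum in (gamma ascending, rho ascending) order —
deterministic and documented. Because kernel entries are pairwise
functions of samples, the per-fold kernels are exact sub-blocks of the
full-sample kernel; the correlation matrix and its PD correction involve
no sample information, so precomputing per-`rho` correlations and
per-`gamma` transforms is a pure speed-up with no fold leakage. AUC is
rank-based with ties averaged (cross-checked against pROC in the tests);
`r_squared()` is the squared sample correlation, with zero-variance inputs
defined as 0 under a warning (a constant predictor has no predictive
correlation).

## The simulator

`simulate_dataset()` emulates the statistical structure of a 16S OTU
table with a phylogenetically clustered outcome signal:

* tree: random topology, exponential branch lengths (`random_tree`);
* composition: ranked log-normal mean proportions (`sdlog = 2`) — a few
  dominant taxa, a long rare tail — with Dirichlet-multinomial
  overdispersion `phi = 0.02`. These defaults are self-contained stand-ins
  chosen to look like real upper-respiratory/gut surveys; any real count
  table can replace them via `estimate_dm()` (method of moments);
* library sizes: negative binomial, mean 5000, size 25 ("dispersion 25"
  is read as the size parameter, variance `mu + mu^2/25`; configurable);
* signal: OTUs are partitioned into `m` clusters by PAM on patristic
  distances; `m_c = floor(m s%)` clusters are selected at a target
  cumulative-abundance level by taking the max/median/min over 1000
  random draws; all OTUs in a cluster share one coefficient
  `b_l ~ N(0, sigma_b^2)` (default 2 continuous, 4 binary);
* noise: for continuous outcomes
  `sigma_e^2 = ((1-v)/v) var(signal)` with `v = 0.8` by default, so the
  OTUs explain exactly 80% of outcome variance by construction; `v = 0.5`
  and `0.33` give the lower signal-to-noise settings. The intercept
  defaults to 0 for both outcome types (balanced classes);
* non-linearity: the signal may enter as `z`, `sqrt(z)` or `1(z != 0)`;
* noisy trees: `permute_tree()` scrambles a percentage of rows/columns of
  the distance matrix jointly, preserving symmetry and the distance
  multiset;
* balanced binary designs: exact case/control quotas are met by batch
  rejection sampling with the cluster coefficients drawn once and held
  fixed.

What the simulator does **not** emulate: real phylogenetic signal in the
composition itself (abundances are exchangeable given the mean vector),
taxonomic correlation between abundance and tree position, sequencing
artifacts, or batch effects. Passing the directional experiments below
therefore demonstrates correctness of the machinery and the intended
behavior of the tuning parameters, not field performance on any
particular cohort.

## Preprocessing pipeline

Stage order is fixed: Bray-Curtis sample-outlier filter → OTU filters →
size-factor normalization → winsorization → square-root transform.
Choices:

* the outlier index (median distance to other samples over the median of
  those medians, cutoff 2) is computed on proportions, removing
  library-size artifacts; identical samples (zero median distance) are
  kept with a warning — identical is not outlying;
* OTU filters: prevalence < 10% or median non-zero count < 10;
* size factors: geometric mean over samples of the median count ratio on
  shared taxa, robust to zero inflation. The geometric mean includes the
  trivial self-ratio (divisor `n` rather than `n-1`): with the `n-1`
  divisor a pure library-size scaling `lambda_j` is recovered as
  `lambda_j^{n/(n-1)}` rather than `lambda_j`, a small-sample distortion
  the self-ratio removes exactly. Factors are rescaled to geometric
  mean 1;
* winsorization caps each taxon at its 97% quantile using the
  inverse-ECDF convention (R quantile type 1). An interpolated quantile
  shifts after capping, so capping would not be idempotent; an order
  statistic is, and idempotence is the property a capping operator should
  have;
* the square-root transform (and any outcome transform) is a flag, not
  hard-wired.

## Scale of the validation experiments

The heavy checks in the test suite run reduced-scale versions of the
simulation sweep, sized for a single CPU: the tree-aware vs tree-agnostic
comparison uses `n_train = 100`, `n_test = 200`, `p = 200`, 10 replicates,
full default grids; the presence/absence and `rho`-selection experiments
use `p = 100` (the latter with `gamma` restricted to `{0.5, 1}`, since
`rho` selection is what it measures). Variance-ratio recovery uses
`n = 300` with 50 replicates. These sizes were chosen once, as the
smallest at which the directional effects are comfortably reproducible.

## Known limitations

* A single variance component: no sample-level random effects, so
  longitudinal or family designs are out of scope.
* PQL is a first-order approximation; for small `n` and strong effects
  its variance components are biased toward zero, and under separation
  the fit is flagged rather than resolved (no Firth-type correction).
* The kernel list is fixed: no composite tree + non-tree kernels.
* `cross_validate()` reports fold-averaged criteria for selection; it does
  not nest CV for an unbiased generalization estimate, though held-out
  evaluation is trivial to arrange as in the README example.
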