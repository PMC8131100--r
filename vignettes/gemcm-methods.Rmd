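---
title: "Methods: gene-expression-modulated multifactorial causal modelling"
author: "gemcm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-expression-modulated multifactorial causal modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model and its assumptions

`gemcm` treats the brain as a multifactorial dynamical system. Each of
`n_rois` grey-matter regions carries `n_factors` macroscopic states
(amyloid-β, tau, cerebral blood flow, glucose metabolism, resting functional
activity, grey-matter density, in the six-factor configuration), and the
local rate of change of factor $m$ in region $i$ is

$$\frac{dS_i^m}{dt} \;=\; \sum_{n=1}^{N_f}\Big(\alpha_0^{n\to m}
  + \sum_{k=1}^{N_g}\alpha_k^{n\to m} G_i^k\Big) S_i^n
  \;+\; \beta^m \sum_{j\neq i} C_{ji}\,(S_j^m - S_i^m).$$

The assumptions this encodes:

* **Local interactions are linear in the states** and modulated additively by
  the regional expression $G_i^k$ of each gene (z-scored per gene across
  regions, so $\alpha_k^{n\to m}$ measures the change in the $n\to m$
  coupling per SD of expression).
* **One static expression template serves all subjects.** Subject-specific
  deviations are absorbed by the fitted $\alpha_k^{n\to m}$, which are
  therefore interpretable as individual gene-dysregulation scores rather
  than as literal transcription rates.
* **Spreading is diffusive**: each factor exchanges alteration along
  connectome edges in proportion to inter-regional differences, with one
  scalar coefficient $\beta^m$ per factor. With a symmetric connectome this
  term conserves the factor's total, which the tests assert.

A deliberate structural decision concerns the spreading term's
parameterization: it enters the regression as a *single* coefficient per
target factor multiplying $\sum_j C_{ji}(S_j^m - S_i^m)$. This is what makes
the per-factor coefficient count $N_f + N_g N_f + 1$ — 5863 for 976 genes
and six factors, 5856 of them gene-modulation terms — and those counts are
pinned by tests. Alternative readings (e.g. region-specific spreading
weights) do not produce that count.

Fitting is exactly linear by construction. Derivatives are finite
differences between consecutive visits, divided by the inter-visit interval
in years (annualized, so parameters are comparable across irregular
schedules), concatenated time-major into a vector of
$N_{rois}(N_{times}-1)$ values. The design matrix evaluates all
right-hand-side terms at each interval's left endpoint (the explicit-Euler
convention). Trajectories generated by forward Euler at the observation
times therefore satisfy `derivatives = X %*% theta` to machine precision, an
identity the acceptance tests check at $10^{-8}$.

## Per-subject inference: the horseshoe

With $p = 5863 \gg n$, per-subject estimation uses Bayesian linear
regression with the horseshoe prior: $\beta_j \sim N(0, \sigma^2\tau^2
\lambda_j^2)$ with half-Cauchy local scales $\lambda_j$ and global scale
$\tau$, sampled by Gibbs using the inverse-gamma auxiliary-variable
representation of the half-Cauchy. The coefficient update uses a $p\times p$
Cholesky solve when $p \le n$ and the exact $O(n^2 p)$ data-augmentation
Gaussian sampler when $p > n$ (`sampler_mode = "auto"`); both samplers target
the same conditional, and a test verifies their posterior means agree within
Monte-Carlo error (batch-means standard errors, since the chains are
autocorrelated). The point estimate is the mean of the kept draws (defaults:
1000 burn-in, 500 kept). The sampler is implemented in C++ (RcppArmadillo)
but draws all randomness from R's RNG, so results are bit-reproducible under
the configuration seed.

Numerical choices: design columns are scaled internally to unit
root-mean-square — *not centred*, because the model has no intercept — and
coefficients are rescaled afterwards; `y` is left untouched. Hyperpriors are
the standard vague inverse-gamma forms; scale variables are clamped to
$[10^{-12}, 10^{12}]$ to prevent overflow in degenerate conditionals.
Zero-variance columns get scale 1 and are shrunk to zero rather than
dropped, preserving the documented column layout.

## Population analysis

Per-subject gene-modulation estimates are stacked into a subjects ×
parameters matrix (gene-major within target factor, target factors in
order). The analysis then proceeds:

1. **Stability filter**: keep parameters whose t-based CI of the
   across-subject mean at `ci_level = 0.99` excludes zero. Among the ways a
   "99% CI" can be computed (t-based vs percentile bootstrap), the t
   interval is chosen for determinism and speed; on pure-noise parameters
   the filter retains
   ≈1%, which a calibration test asserts.
2. **Behavioural PLS**: both blocks are z-scored column-wise and the
   cross-block *correlation* matrix (not covariance — parameters and scores
   have incommensurate units) is decomposed by SVD. Explained variance of
   component $i$ is $s_i^2/\sum s^2$. Components are oriented so the
   cognitive score with the largest |loading| loads positively.
3. **Permutation test**: cognitive rows are shuffled, singular values
   recomputed, and p-values use the add-one estimator
   $(1 + \#\{s^{perm} \ge s^{obs}\})/(n_{perm}+1)$, so they are never zero
   and type-I error is nominal (asserted at $\alpha = 0.05$ over 500 null
   repetitions).
4. **Bootstrap ratios**: subjects are resampled with replacement, the PLS is
   recomputed, and bootstrap salience matrices are aligned to the original
   by orthogonal Procrustes rotation of the score-loading block (a sign-flip
   alternative is available). The ratio is the original salience divided by
   its bootstrap SE; $|ratio| > 2.58$ selects parameters. Variability is
   measured on the singular-value-weighted saliences $US$: unit-norm
   saliences would understate the SE, because resampling noise inflates the
   norm of the bootstrap cross-correlation matrix whenever many parameters
   are carried, making the ratios anticonservative (we measured null-ratio
   SDs of ≈1.3 with unit-norm saliences versus ≈1.07 with the weighted
   form). Only components with permutation $p < 0.05$ proceed to the
   bootstrap; the selected parameters are ranked by |salience| (ties broken
   by label) into a gene × source-factor × target-factor table.

## Transcriptome preparation

The template-building stage mirrors how regional expression templates are
derived from point-sampled microarray data: Gaussian kernel regression
$\hat g(q) = \sum_s w(q,s)\, v_s / \sum_s w(q,s)$ with
$w = \exp(-\lVert q-s\rVert^2/2\sigma^2)$ interpolates samples over space
(predictions are provably convex combinations of sample values);
leave-one-out cross-validated Pearson correlation selects one representative
probe per gene (probes with <3 samples or zero variance are assigned
$-\infty$; ties break to the lowest index); samples are averaged within
regions, unsampled regions are filled by kernel regression at their
centroids, and each gene is z-scored across regions with the population-SD
convention (divisor $n$ — any consistent convention works; this one is
declared and enforced by the `gene_template` validator). Genes constant
across regions cannot be z-scored and are excluded with a warning.

The kernel bandwidth $\sigma$ is a **required argument with no default**:
no principled universal value exists, and fixing one silently would bake an
arbitrary constant into every downstream result. The LOOCV machinery makes
bandwidth sweeps straightforward.

## Cohort screening

* **Mahalanobis outlier screen**: a subject is an outlier when its squared
  distance to the modality's sample mean exceeds the upper-α chi-square
  quantile with `n_features` degrees of freedom (α = 0.05 by default). The
  statistic is affine-invariant, which a property test asserts.
* **Trimmed-scores regression imputation**: missing modalities are imputed
  by the iterative TSR-PCA scheme — column-mean initialization, rank-$r$
  PCA, least-squares scores from each row's observed block, reconstruction
  of the missing block, iterated to a relative change below `tol`. The rank
  defaults to the smallest explaining 90% of variance. The exact variant in
  the cited literature family is not fully specified; this is the standard
  iterative scheme, and a rank-1 matrix with 10% masking is recovered to
  $10^{-6}$ in tests.
* **Cognitive slopes**: per subject and score, the OLS slope of score
  against *age* (not time-from-baseline), in score points per year; slopes
  with fewer than two usable visits are `NA`, never zero-filled. No
  covariate adjustment is performed (none is specified for the modelled
  quantity).

## The synthetic-cohort generator

The generator is first-class, tested code that defines the study conditions
under which the pipeline is validated. Defaults (a `cohort_config()`):

| parameter | default | rationale |
|---|---|---|
| `n_subjects` | 40 | large enough for stable across-subject CIs, small enough for desk-scale runs |
| `n_rois` | 30 | compact stand-in for a 138-region parcellation |
| `n_genes` | 50 | compact stand-in for the 976-gene template |
| `n_timepoints` / `dt_years` | 5 / 1 | longitudinal imaging cohorts average ~4.7 visits at roughly annual spacing |
| `n_cog_visits` / `cog_dt_years` | 7 / 1 | cognitive follow-up is typically longer (~7 visits) |
| `connectome_density` | 0.2 | sparse heavy-tailed (log-normal) weights mimic streamline counts |
| `gene_spatial_lengthscale` | 15 mm | cortical expression maps decorrelate over millimetre-to-centimetre scales; much longer lengthscales make distinct genes collinear at a coarse parcellation |
| `n_active_params` | 10 per target factor | population analyses of this model class find only a small percentage of gene-imaging parameters distinct from zero (tens to ~1000 out of ~35000); 10/300 ≈ 3% matches that regime |
| `effect_scale` | 0.05 /yr | active couplings produce a few-percent annual change of signals of magnitude ~1 |
| `obs_noise_sd` | 0.01 | ~1% measurement noise on normalized regional imaging signals |
| `cog_noise_sd` | 0.1 pts/yr | slope noise comparable to the slower cognitive drifts |
| initial states | U[0.5, 1.5] | normalized imaging units; positivity keeps multiplicative terms well-behaved |

Structure: all subjects share a sparse population support per target factor
with mean effects $\pm$`effect_scale`; subject-level variation decomposes
into a component aligned with a latent direction (amplitude
0.5·`effect_scale`, loading on half of each factor's support) and
idiosyncratic variation (0.2·`effect_scale`) confined to the support, so the
exact-sparsity invariant holds. Cognitive slopes equal the projection of the
subject's parameters on the latent direction times a per-score weight
(negative for MMSE/MEM/EF, positive for ADAS), plus `cog_noise_sd` noise
applied to the slope itself — visit-level scores are exactly linear in age,
so with `cog_noise_sd = 0` slopes are exactly collinear with projections.

Trajectories are integrated by forward Euler at the observation times
(`n_substeps = 1`), deliberately matched to the fitting convention so the
inverse problem is exactly solvable at zero noise; `n_substeps > 1` enables
finer integration for discretization-robustness experiments. A magnitude
bound (default $10^3$ in the generator) converts divergence into an error
naming the subject and step.

**What the generator does *not* emulate** — and hence what passing tests do
not show about real data: spatial correlation of measurement noise, shared
(rather than subject-specific) connectomes estimated with tractography
biases, visit-count and spacing heterogeneity, missing modalities,
diagnosis-dependent effect heterogeneity, and any mismatch between the
template and individual transcriptomes. Tests demonstrate the estimator and
analysis chain are correct and calibrated under the stated generative
assumptions, not that real cohorts satisfy those assumptions.

## Known limitations

* When the population analysis is run on *fitted* (rather than true)
  parameters, shrinkage leakage among correlated gene columns spreads the
  latent signal over many estimation-correlated parameters; the stability
  filter then retains more columns and the bootstrap selects
  genuinely-correlated but not-generatively-loaded parameters. This is a
  property of any sparse estimator under collinearity, and is why selected
  "causal" genes warrant external validation.
* Individual $\alpha_k^{n\to m}$ for the same gene across source factors are
  weakly separable when states vary little over time (their design columns
  share the factor $G_i^k$); aggregation over source factors is more stable
  than single entries.
* The permutation test shuffles the cognitive block only; exchangeability
  across subjects is assumed.

## Problem sizes used by the tests and acceptance script

Structural counts run at the full 976-gene size; estimation checks run on
the default 40-subject cohort (≈300 coefficients per factor) with 400
burn-in/300 kept draws, which reproduces the same recovery behaviour as the
1000/500 default at a fraction of the cost; resampling calibrations use 500
null repetitions at `n_perm = 199`, and the planted-signal pipeline runs at
`n_perm = n_boot = 1000`. These sizes are the package's declared validation
conditions; confirmatory analyses on real data should use the 10000-draw
resampling defaults.
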