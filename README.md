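# gemcm — gene-expression-modulated multifactorial causal modelling

`gemcm` fits a personalized generative model of the aging and
neurodegenerating brain in which **regional gene expression modulates the
interactions among macroscopic biological factors** measured by longitudinal
PET/MRI — amyloid-β burden, tau burden, cerebral blood flow, glucose
metabolism, resting functional activity, and grey-matter density — while each
factor's alterations also spread between regions along an anatomical
connectome. It is aimed at researchers linking transcriptomic maps (e.g.
Allen Human Brain Atlas-style templates) with longitudinal multimodal
neuroimaging and cognitive decline.

## The model

Each brain region `i` carries a state `S_i^m` per factor `m`. Its rate of
change is

```
dS_i^m/dt = Σ_n ( α0^{n→m} + Σ_k α_k^{n→m} G_i^k ) S_i^n
            + β^m Σ_{j≠i} C_ji ( S_j^m − S_i^m )
```

where `G_i^k` is the z-scored expression of gene `k` in region `i`, `C` a
nonnegative zero-diagonal connectome, `α0^{n→m}` the baseline influence of
factor `n` on factor `m`, `α_k^{n→m}` the gene-specific modulation of that
influence (the *transcriptomic-imaging parameters*), and `β^m` a scalar
spreading coefficient. With 976 genes and 6 factors this is
`6 + 976·6 + 1 = 5863` coefficients per subject and target factor, of which
5856 are gene-modulation terms.

Fitting is linear: finite-difference derivatives of each factor are regressed
on a design matrix whose columns are the right-hand-side terms evaluated at
each interval's left endpoint. Because `p ≫ n`, per-subject coefficients are
estimated by **Bayesian sparse regression with a horseshoe prior** (Gibbs
sampling; a fast exact Gaussian update is used when `p > n`). At the
population level, parameters whose across-subject 99% CI excludes zero enter
a **behavioural PLS**: SVD of the parameter-by-cognitive-slope correlation
matrix, permutation tests for component significance, and bootstrap ratios
(threshold 2.58) to select the reliable gene-imaging parameters, which are
then ranked into a gene table.

A first-class synthetic-cohort generator produces templates, connectomes,
trajectories (by the model's own forward dynamics), and cognitive scores
driven by a latent direction in parameter space, so the entire pipeline is
testable end-to-end without any external data.

## Worked example

```r
library(gemcm)

cfg    <- cohort_config(n_subjects = 12, n_rois = 20, n_genes = 30,
                        n_timepoints = 4, seed = 42)
cohort <- gen_cohort(cfg)
#> <synthetic_cohort> 12 subjects, 6 factors x 20 regions x 4 time points, 30 genes (seed 42)

fit <- fit_cohort(cohort$subjects, cohort$template, cohort$connectome,
                  horseshoe_config(n_burn = 300, n_keep = 200, seed = 42))
round(head(fit$r2, 3), 3)
#>       F1    F2    F3    F4    F5    F6
#> S1 0.996 0.990 0.998 0.989 0.992 0.998
#> S2 0.996 0.986 0.993 0.991 0.997 0.996
#> S3 0.990 0.994 0.996 0.992 0.998 0.995

slopes <- cognitive_slopes(cohort$cognitive)[rownames(fit$param_matrix), ]
truth  <- stack_gene_params(cohort$true_params, cohort$template$gene_ids)
res    <- analyze_parameters(truth, slopes, n_perm = 1000, n_boot = 1000, seed = 42)
res
#> <pls_result> 5 components; explained variance: 91% 3.82% 3.46% 1.48% 0.241%
#>   permutation p-values: 0.000999 0.821 0.119 0.285 0.346
head(res$gene_table, 3)
#>   gene source_factor target_factor   salience     ratio
#> 2   g2            F2            F1 -0.1935207 -9.208334
#> 4   g9            F6            F1  0.1910850  9.667711
#> 9  g13            F5            F2 -0.1902960 -8.063844
```

The per-subject, per-factor `R2` values show how well the fitted model
reproduces the observed longitudinal derivatives. The PLS finds one
significant component (permutation p ≈ 0.001) capturing 91% of the
parameter-cognition cross-correlation, and the gene table names the
gene-by-interaction parameters whose bootstrap ratios exceed 2.58 — here
drawn from the entries the generator actually loaded onto cognition. At this
deliberately small demo size the per-subject parameter estimates correlate
with the generating truth at r ≈ 0.6 on average; at the package's default
study conditions (40 subjects, 30 regions, 50 genes, 5 visits) mean recovery
is ≈ 0.94 (see the methods vignette for the conditions and their rationale).

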