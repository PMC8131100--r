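#' Bayesian horseshoe sparse regression
#'
#' Per-subject, per-factor fitting maps the model's design matrix to the
#' observed derivative vector with a global-local shrinkage (horseshoe) prior,
#' which leaves large coefficients nearly unshrunk while pulling the bulk of
#' the high-dimensional coefficient vector towards zero.  The point estimate
#' is the mean of the kept posterior draws.
#'
#' @name inference
NULL

#' Sampler configuration
#'
#' @param n_burn burn-in Gibbs iterations discarded (default 1000).
#' @param n_keep posterior draws kept and averaged (default 500).
#' @param seed integer seed; every fit is reproducible given the config.
#' @param sampler_mode `"auto"` (fast sampler when p > n), `"standard"`
#'   (p x p Cholesky), or `"fast_p_gt_n"`.
#' @param keep_samples retain the `n_keep x p` draw matrix in the result.
#' @return a `horseshoe_config` list.
#' @export
horseshoe_config <- function(n_burn = 1000L, n_keep = 500L, seed = 1L,
                             sampler_mode = c("auto", "standard", "fast_p_gt_n"),
                             keep_samples = FALSE) {
  structure(list(n_burn = check_count(n_burn, "n_burn"),
                 n_keep = check_count(n_keep, "n_keep"),
                 seed = check_count(seed, "seed", min = 0L),
                 sampler_mode = match.arg(sampler_mode),
                 keep_samples = isTRUE(keep_samples)),
            class = "horseshoe_config")
}

#' Fit a linear model with the horseshoe prior
#'
#' Gibbs sampler over the horseshoe hierarchy: Gaussian likelihood, half-Cauchy
#' local (`lambda_j`) and global (`tau`) scales represented through
#' inverse-gamma auxiliary variables, vague inverse-gamma prior on the noise
#' variance.  Columns of `X` are scaled internally to unit root-mean-square
#' (no centring: the model carries no intercept) and coefficients are
#' transformed back to the original scale; `y` is left unscaled.
#'
#' @param X numeric design matrix `n x p`.
#' @param y numeric response vector of length `n`.
#' @param cfg a [horseshoe_config()].
#' @return a `posterior_summary` list: `coef_mean` (posterior-mean
#'   coefficients, original scale), `sigma2_mean`, `global_shrinkage_mean`,
#'   `sampler_mode`, and `coef_samples` when requested.
#' @export
horseshoe_fit <- function(X, y, cfg = horseshoe_config()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) == 0L || ncol(X) == 0L) stop_invalid("X must be non-empty")
  if (length(y) != nrow(X)) stop_invalid("length(y) must equal nrow(X)")
  if (!all(is.finite(X)) || !all(is.finite(y))) stop_invalid("X and y must be finite")
  stopifnot(inherits(cfg, "horseshoe_config"))

  scale_rms <- sqrt(colMeans(X^2))
  scale_rms[scale_rms == 0] <- 1
  Xs <- sweep(X, 2L, scale_rms, "/")
  mode_code <- match(cfg$sampler_mode, c("auto", "standard", "fast_p_gt_n")) - 1L

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  fit <- .hs_gibbs(Xs, y, cfg$n_burn, cfg$n_keep, mode_code, cfg$keep_samples)

  fit$coef_mean <- as.numeric(fit$coef_mean) / scale_rms
  names(fit$coef_mean) <- colnames(X)
  if (!is.null(fit$coef_samples)) {
    fit$coef_samples <- sweep(fit$coef_samples, 2L, scale_rms, "/")
    colnames(fit$coef_samples) <- colnames(X)
  }
  structure(fit, class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("<posterior_summary> p = ", length(x$coef_mean),
      ", sampler = ", x$sampler_mode,
      ", sigma2 = ", signif(x$sigma2_mean, 4),
      ", tau = ", signif(x$global_shrinkage_mean, 4), "\n", sep = "")
  invisible(x)
}

#' Fit the full model for one subject
#'
#' For each target factor, builds the derivative vector and design matrix,
#' runs [horseshoe_fit()], reshapes posterior means into a [factor_params()],
#' and computes the in-sample coefficient of determination of the predicted
#' derivatives.
#'
#' @param ts a [subject_timeseries()] with at least 2 time points.
#' @param template a [gene_template()].
#' @param conn connectome matrix.
#' @param cfg a [horseshoe_config()]; each factor's chain uses a sub-seed
#'   deterministically derived from `cfg$seed`.
#' @param verbose print per-factor progress.
#' @return list with `params` (list of `factor_params` per factor), `r2`
#'   (named numeric per factor), `mean_r2`, `sampler_modes`.
#' @export
fit_subject <- function(ts, template, conn, cfg = horseshoe_config(),
                        verbose = FALSE) {
  stopifnot(inherits(ts, "subject_timeseries"))
  template <- align_template(template, ts)
  n_factors <- dim(ts$values)[1L]
  n_genes <- nrow(template$matrix)
  params <- vector("list", n_factors)
  r2 <- setNames(numeric(n_factors), ts$factor_names)
  modes <- character(n_factors)
  for (m in seq_len(n_factors)) {
    y <- finite_difference_derivatives(ts, m)
    X <- build_design_matrix(ts, template, conn, m)
    cfg_m <- cfg
    cfg_m$seed <- split_seed(cfg$seed, "fit_factor", m)
    fit <- horseshoe_fit(X, as.numeric(y), cfg_m)
    params[[m]] <- unflatten_params(fit$coef_mean, n_genes, n_factors,
                                    ts$factor_names[m])
    r2[m] <- r2_score(as.numeric(y), as.numeric(X %*% fit$coef_mean))
    modes[m] <- fit$sampler_mode
    if (verbose)
      message("factor ", ts$factor_names[m], ": R2 = ", signif(r2[m], 4),
              " (", fit$sampler_mode, ")")
  }
  list(params = params, r2 = r2, mean_r2 = mean(r2, na.rm = TRUE),
       sampler_modes = modes)
}
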