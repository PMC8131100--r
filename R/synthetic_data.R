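#' Synthetic cohorts
#'
#' Generates complete synthetic study cohorts with the statistical structure
#' the analysis pipeline assumes: a spatially autocorrelated regional
#' gene-expression template, a sparse heavy-tailed connectome, per-subject
#' longitudinal factor trajectories produced by the model's own forward
#' dynamics plus observation noise, and cognitive visit tables whose
#' per-subject slopes are driven by a latent direction in parameter space.
#' Every stage of the pipeline is therefore testable end-to-end with no
#' external data.
#'
#' @name synthetic_data
NULL

#' Synthetic cohort configuration
#'
#' Defaults describe a compact cohort whose signal-to-noise regime mirrors
#' longitudinal multimodal imaging studies: normalized regional signals near
#' 1, annual visits, ~1% measurement noise, and sparse gene-modulation
#' effects an order of magnitude above the noise floor of the derivative
#' regression.
#'
#' @param n_subjects number of subjects (default 40).
#' @param n_rois number of grey-matter regions (default 30).
#' @param n_genes number of genes in the template (default 50).
#' @param n_factors number of macroscopic factors (default 6).
#' @param n_timepoints imaging visits per subject (default 5).
#' @param dt_years inter-visit interval in years (default 1).
#' @param connectome_density expected off-diagonal nonzero fraction (default
#'   0.2).
#' @param gene_spatial_lengthscale kernel lengthscale (mm) of the synthetic
#'   expression fields; region coordinates live in a 100 mm box (default 15,
#'   matching the millimetre-scale spatial autocorrelation of cortical
#'   expression maps while keeping distinct genes distinguishable at a
#'   coarse parcellation).
#' @param n_active_params nonzero gene-modulation entries per target factor
#'   (default 10, i.e. ~3% of the gene-modulation block — population-level
#'   analyses of this model class find only a small percentage of
#'   gene-imaging parameters distinguishable from zero, so the generator
#'   defaults to comparable sparsity).
#' @param effect_scale magnitude of active gene-modulation coefficients
#'   (default 0.05 per year).
#' @param obs_noise_sd i.i.d. observation noise added to trajectories
#'   (default 0.01).
#' @param cog_noise_sd noise on the constructed cognitive slopes (default
#'   0.1 score points per year).
#' @param n_cog_scores number of cognitive scores (default 5: MMSE, ADAS-11,
#'   ADAS-13, MEM, EF).
#' @param n_cog_visits,cog_dt_years cognitive visit count and spacing
#'   (defaults 7 visits, 1 year).
#' @param n_substeps Euler sub-steps per interval for trajectory generation
#'   (default 1: generator matched to the fitting convention, so the inverse
#'   problem is exactly linear at zero noise).
#' @param seed integer seed (default 1).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 40L, n_rois = 30L, n_genes = 50L,
                          n_factors = 6L, n_timepoints = 5L, dt_years = 1,
                          connectome_density = 0.2,
                          gene_spatial_lengthscale = 15,
                          n_active_params = 10L, effect_scale = 0.05,
                          obs_noise_sd = 0.01, cog_noise_sd = 0.1,
                          n_cog_scores = 5L, n_cog_visits = 7L,
                          cog_dt_years = 1, n_substeps = 1L, seed = 1L) {
  cfg <- list(
    n_subjects = check_count(n_subjects, "n_subjects"),
    n_rois = check_count(n_rois, "n_rois", min = 2L),
    n_genes = check_count(n_genes, "n_genes"),
    n_factors = check_count(n_factors, "n_factors", min = 2L),
    n_timepoints = check_count(n_timepoints, "n_timepoints", min = 2L),
    dt_years = check_scalar(dt_years, "dt_years", 0, lower_open = TRUE),
    connectome_density = check_scalar(connectome_density, "connectome_density",
                                      0, 1, lower_open = TRUE),
    gene_spatial_lengthscale = check_scalar(gene_spatial_lengthscale,
                                            "gene_spatial_lengthscale", 0,
                                            lower_open = TRUE),
    n_active_params = check_count(n_active_params, "n_active_params", min = 0L),
    effect_scale = check_scalar(effect_scale, "effect_scale"),
    obs_noise_sd = check_scalar(obs_noise_sd, "obs_noise_sd", 0),
    cog_noise_sd = check_scalar(cog_noise_sd, "cog_noise_sd", 0),
    n_cog_scores = check_count(n_cog_scores, "n_cog_scores"),
    n_cog_visits = check_count(n_cog_visits, "n_cog_visits", min = 2L),
    cog_dt_years = check_scalar(cog_dt_years, "cog_dt_years", 0, lower_open = TRUE),
    n_substeps = check_count(n_substeps, "n_substeps"),
    seed = check_count(seed, "seed", min = 0L))
  if (cfg$n_active_params > cfg$n_genes * cfg$n_factors)
    stop_invalid("n_active_params must be <= n_genes * n_factors (per target factor)")
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic anatomical connectome
#'
#' Symmetric, nonnegative, zero-diagonal coupling matrix.  Edges are present
#' independently with probability `density`; edge weights are log-normal
#' (heavy-tailed positive, mimicking streamline counts).
#'
#' @param n_rois number of regions (>= 2).
#' @param density expected off-diagonal nonzero fraction, in (0, 1].
#' @param seed integer seed.
#' @param meanlog,sdlog log-normal weight parameters.
#' @return `n_rois x n_rois` numeric matrix.
#' @export
gen_connectome <- function(n_rois, density, seed = 1L, meanlog = 0, sdlog = 1) {
  n_rois <- check_count(n_rois, "n_rois", min = 2L)
  density <- check_scalar(density, "density", 0, 1, lower_open = TRUE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(check_count(seed, "seed", min = 0L))
  n_edges <- n_rois * (n_rois - 1L) / 2L
  present <- runif(n_edges) < density
  w <- numeric(n_edges)
  w[present] <- rlnorm(sum(present), meanlog, sdlog)
  C <- matrix(0, n_rois, n_rois)
  C[upper.tri(C)] <- w
  C <- C + t(C)
  dimnames(C) <- list(paste0("R", seq_len(n_rois)), paste0("R", seq_len(n_rois)))
  C
}

sq_exp_cov <- function(coords, lengthscale, nugget = 1e-8) {
  d2 <- as.matrix(stats::dist(coords))^2
  exp(-d2 / (2 * lengthscale^2)) + diag(nugget, nrow(coords))
}

#' Generate a spatially autocorrelated gene-expression template
#'
#' Regions receive uniform random 3-d coordinates in a 100 mm box; each gene
#' is an independent draw from a Gaussian process with squared-exponential
#' covariance at those coordinates (lengthscale in mm), then z-scored across
#' regions.  Coordinates are retained in the result for kernel-regression
#' tests.
#'
#' @param n_genes,n_rois dimensions.
#' @param lengthscale positive spatial lengthscale (mm); large values give
#'   smooth, spatially dependent expression maps.
#' @param seed integer seed.
#' @param box_size coordinate range (default 100 mm).
#' @return a [gene_template()] with `coords` set; the pre-z-scoring fields
#'   are kept in the `raw` attribute.
#' @export
gen_gene_expression <- function(n_genes, n_rois, lengthscale, seed = 1L,
                                box_size = 100) {
  n_genes <- check_count(n_genes, "n_genes")
  n_rois <- check_count(n_rois, "n_rois")
  lengthscale <- check_scalar(lengthscale, "lengthscale", 0, lower_open = TRUE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(check_count(seed, "seed", min = 0L))
  coords <- matrix(runif(n_rois * 3L, 0, box_size), ncol = 3L)
  L <- chol(sq_exp_cov(coords, lengthscale))
  raw <- matrix(rnorm(n_genes * n_rois), nrow = n_genes) %*% L   # genes x regions
  z <- if (n_rois > 1L) zscore_rows(raw) else raw
  dimnames(z) <- list(paste0("g", seq_len(n_genes)), paste0("R", seq_len(n_rois)))
  out <- gene_template(z, coords = coords)
  attr(out, "raw") <- raw
  out
}

default_score_names <- function(n) {
  base <- c("MMSE", "ADAS11", "ADAS13", "MEM", "EF")
  if (n <= length(base)) base[seq_len(n)] else c(base, paste0("SC", seq_len(n - length(base))))
}

# Per-score weights of the latent projection on cognitive slopes
# (signs: MMSE/MEM/EF decline, ADAS scores increase with impairment).
default_score_weights <- function(score_names) {
  w <- c(MMSE = -0.2, ADAS11 = 0.5, ADAS13 = 0.6, MEM = -0.1, EF = -0.1)
  out <- ifelse(score_names %in% names(w), w[score_names], 0.2)
  setNames(as.numeric(out), score_names)
}

default_score_baselines <- function(score_names) {
  b <- c(MMSE = 29, ADAS11 = 6, ADAS13 = 9, MEM = 0.5, EF = 0.5)
  out <- ifelse(score_names %in% names(b), b[score_names], 0)
  setNames(as.numeric(out), score_names)
}

#' Generate a complete synthetic cohort
#'
#' Draws a gene-expression template and connectome, then per subject: a
#' sparse set of true model parameters (a common population support of
#' `n_active_params` gene-modulation entries per target factor, with
#' subject-level variation partly aligned with a latent direction), forward
#' trajectories by Euler integration of the model from random positive
#' initial states plus observation noise, and a cognitive visit table whose
#' per-subject slopes equal the projection of the subject's parameters on the
#' latent direction times a per-score weight, plus noise.
#'
#' @param cfg a [cohort_config()].
#' @return a `synthetic_cohort` list: `template`, `connectome`, `subjects`
#'   (list of [subject_timeseries()]), `true_params` (per subject, list of
#'   [factor_params()] per factor), `cognitive` (long-format visit table),
#'   `slopes_true` (subjects x scores matrix), `true_latent` (named vector
#'   over stacked gene-modulation parameters), `latent_projection`,
#'   `config`.
#' @export
gen_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  K <- cfg$n_genes; F_ <- cfg$n_factors; R <- cfg$n_rois
  template <- gen_gene_expression(K, R, cfg$gene_spatial_lengthscale,
                                  seed = split_seed(cfg$seed, "template"))
  conn <- gen_connectome(R, cfg$connectome_density,
                         seed = split_seed(cfg$seed, "connectome"))
  factor_names <- paste0("F", seq_len(F_))
  times <- seq(0, by = cfg$dt_years, length.out = cfg$n_timepoints)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  # Population-level structure: common sparse support and mean effects.
  set.seed(split_seed(cfg$seed, "population"))
  n_gene_params <- K * F_
  support <- lapply(seq_len(F_), function(m)
    sort(sample.int(n_gene_params, cfg$n_active_params)))
  mean_effect <- lapply(seq_len(F_), function(m)
    sample(c(-1, 1), cfg$n_active_params, replace = TRUE) * cfg$effect_scale)
  alpha0_pop <- matrix(rnorm(F_ * F_, 0, 0.02), F_, F_)   # [source, target]
  beta_pop <- runif(F_, 0.005, 0.02)

  # Latent direction: loads on half of each target factor's active entries.
  latent_blocks <- lapply(seq_len(F_), function(m) {
    v <- numeric(n_gene_params)
    n_load <- max(1L, floor(cfg$n_active_params / 2))
    loaded <- support[[m]][seq_len(n_load)]
    v[loaded] <- sample(c(-1, 1), n_load, replace = TRUE)
    v
  })
  true_latent <- unlist(latent_blocks)
  gene_labels <- unlist(lapply(seq_len(F_), function(m) {
    lab <- param_labels(template$gene_ids, factor_names, factor_names[m])
    lab[F_ + seq_len(n_gene_params)]
  }))
  names(true_latent) <- gene_labels

  latent_amp <- 0.5 * abs(cfg$effect_scale)   # latent-aligned subject variation
  idio_sd <- 0.2 * abs(cfg$effect_scale)      # idiosyncratic variation on support

  score_names <- default_score_names(cfg$n_cog_scores)
  weights <- default_score_weights(score_names)
  baselines <- default_score_baselines(score_names)

  subjects <- vector("list", cfg$n_subjects)
  true_params <- vector("list", cfg$n_subjects)
  z_latent <- numeric(cfg$n_subjects)
  proj <- numeric(cfg$n_subjects)
  cog_rows <- vector("list", cfg$n_subjects)
  slopes_true <- matrix(NA_real_, cfg$n_subjects, length(score_names),
                        dimnames = list(paste0("S", seq_len(cfg$n_subjects)),
                                        score_names))

  for (s in seq_len(cfg$n_subjects)) {
    set.seed(split_seed(cfg$seed, "subject", s))
    z_s <- rnorm(1)
    z_latent[s] <- z_s
    params <- vector("list", F_)
    for (m in seq_len(F_)) {
      gene_vec <- numeric(n_gene_params)
      gene_vec[support[[m]]] <- mean_effect[[m]] +
        rnorm(cfg$n_active_params, 0, idio_sd)
      gene_vec <- gene_vec + z_s * latent_amp * latent_blocks[[m]]
      # keep exact sparsity: latent loads only inside the support by design
      alpha_gene <- matrix(gene_vec, nrow = K, ncol = F_, byrow = TRUE)
      params[[m]] <- factor_params(
        alpha0_pop[, m] + rnorm(F_, 0, 0.005),
        alpha_gene, beta_pop[m] * runif(1, 0.8, 1.2), factor_names[m])
    }
    true_params[[s]] <- params

    s0 <- matrix(runif(F_ * R, 0.5, 1.5), F_, R)
    ts <- tryCatch(
      simulate_forward(params, s0, times, template, conn,
                       n_substeps = cfg$n_substeps, magnitude_bound = 1e3,
                       factor_names = factor_names,
                       region_ids = template$region_ids),
      gemcm_simulation_unstable = function(e)
        stop(errorCondition(paste0("subject ", s, ": ", conditionMessage(e)),
                            class = c("gemcm_simulation_unstable", "error"))))
    if (cfg$obs_noise_sd > 0)
      ts$values <- ts$values + array(rnorm(length(ts$values), 0, cfg$obs_noise_sd),
                                     dim = dim(ts$values))
    subjects[[s]] <- ts

    proj[s] <- sum(unlist(lapply(seq_len(F_), function(m)
      as.vector(t(params[[m]]$alpha_gene)))) * true_latent)
    slopes <- proj[s] * weights +
      if (cfg$cog_noise_sd > 0) rnorm(length(weights), 0, cfg$cog_noise_sd) else 0
    slopes_true[s, ] <- slopes
    age0 <- runif(1, 60, 80)
    ages <- age0 + seq(0, by = cfg$cog_dt_years, length.out = cfg$n_cog_visits)
    cog_rows[[s]] <- data.frame(
      subject_id = paste0("S", s),
      age = rep(ages, times = length(score_names)),
      score_name = rep(score_names, each = length(ages)),
      value = as.vector(vapply(score_names, function(sc)
        baselines[sc] + slopes[sc] * (ages - age0), numeric(length(ages)))),
      stringsAsFactors = FALSE)
  }
  names(subjects) <- names(true_params) <- paste0("S", seq_len(cfg$n_subjects))

  structure(list(template = template, connectome = conn, subjects = subjects,
                 true_params = true_params,
                 cognitive = do.call(rbind, cog_rows),
                 slopes_true = slopes_true, true_latent = true_latent,
                 latent_projection = setNames(proj, names(subjects)),
                 score_weights = weights, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$config
  cat("<synthetic_cohort> ", cfg$n_subjects, " subjects, ", cfg$n_factors,
      " factors x ", cfg$n_rois, " regions x ", cfg$n_timepoints,
      " time points, ", cfg$n_genes, " genes (seed ", cfg$seed, ")\n", sep = "")
  invisible(x)
}

#' Stack gene-modulation parameters across subjects
#'
#' Builds the subjects-by-parameters matrix analysed at population level: per
#' subject, the gene-modulation blocks of all target factors are flattened
#' (gene-major within target, targets in factor order) and concatenated.
#' Baseline and spreading terms are excluded.
#'
#' @param params_per_subject list over subjects of lists of [factor_params()].
#' @param gene_ids,factor_names labels used to name columns.
#' @return numeric matrix subjects x (n_factors^2 * n_genes) with descriptive
#'   column labels.
#' @export
stack_gene_params <- function(params_per_subject, gene_ids = NULL,
                              factor_names = NULL) {
  stopifnot(length(params_per_subject) >= 1L)
  first <- params_per_subject[[1L]]
  F_ <- length(first)
  K <- nrow(first[[1L]]$alpha_gene)
  gene_ids <- gene_ids %||% paste0("g", seq_len(K))
  factor_names <- factor_names %||% paste0("F", seq_len(F_))
  labels <- unlist(lapply(seq_len(F_), function(m) {
    lab <- param_labels(gene_ids, factor_names, factor_names[m])
    lab[F_ + seq_len(K * F_)]
  }))
  out <- t(vapply(params_per_subject, function(pl)
    unlist(lapply(pl, function(p) as.vector(t(p$alpha_gene)))),
    numeric(F_ * K * F_)))
  colnames(out) <- labels
  rownames(out) <- names(params_per_subject)
  out
}
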