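#' Pipeline orchestration
#'
#' Composes the three stages — simulate (optional), fit, analyze — over a
#' directory layout, writing a JSON manifest per stage so that identical
#' configurations reproduce identical numeric outputs.
#'
#' @name pipeline
NULL

#' Pipeline run configuration
#'
#' @param out_dir output directory (created).
#' @param cohort_dir directory containing a serialized cohort; `NULL` to
#'   generate one from `cohort` into `out_dir/cohort`.
#' @param cohort a [cohort_config()] used when simulating (default:
#'   package defaults).
#' @param horseshoe a [horseshoe_config()] for the fitting stage.
#' @param ci_level,n_perm,n_boot,threshold population-analysis settings.
#' @param seed master seed; fans out deterministically to every stage.
#' @param verbose print progress messages.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, cohort_dir = NULL, cohort = cohort_config(),
                       horseshoe = horseshoe_config(),
                       ci_level = 0.99, n_perm = 10000L, n_boot = 10000L,
                       threshold = 2.58, seed = 1L, verbose = TRUE) {
  if (!is.null(cohort_dir) && !dir.exists(cohort_dir))
    stop_invalid("cohort_dir does not exist: ", cohort_dir)
  structure(list(out_dir = out_dir, cohort_dir = cohort_dir, cohort = cohort,
                 horseshoe = horseshoe, ci_level = ci_level,
                 n_perm = check_count(n_perm, "n_perm"),
                 n_boot = check_count(n_boot, "n_boot"),
                 threshold = check_scalar(threshold, "threshold", 0),
                 seed = check_count(seed, "seed", min = 0L),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Fit every subject of a cohort
#'
#' @param subjects named list of [subject_timeseries()].
#' @param template a [gene_template()].
#' @param conn connectome matrix.
#' @param cfg a [horseshoe_config()]; each subject gets a deterministic
#'   sub-seed, so subject order (or parallel execution) cannot change
#'   results.
#' @param verbose print per-subject progress.
#' @return list with `fits` (per-subject [fit_subject()] results), `r2`
#'   (subjects x factors matrix), `param_matrix` (stacked gene-modulation
#'   estimates, subjects x parameters).
#' @export
fit_cohort <- function(subjects, template, conn, cfg = horseshoe_config(),
                       verbose = FALSE) {
  ids <- names(subjects) %||% paste0("S", seq_along(subjects))
  fits <- vector("list", length(subjects))
  for (s in seq_along(subjects)) {
    cfg_s <- cfg
    cfg_s$seed <- split_seed(cfg$seed, "fit_subject", s)
    t0 <- proc.time()[["elapsed"]]
    fits[[s]] <- fit_subject(subjects[[s]], template, conn, cfg_s)
    if (verbose)
      message("subject ", ids[s], ": mean R2 = ",
              signif(fits[[s]]$mean_r2, 4), " (",
              signif(proc.time()[["elapsed"]] - t0, 3), " s)")
  }
  names(fits) <- ids
  r2 <- t(vapply(fits, function(f) f$r2, fits[[1L]]$r2))
  pm <- stack_gene_params(lapply(fits, function(f) f$params),
                          template$gene_ids,
                          subjects[[1L]]$factor_names)
  rownames(pm) <- ids
  list(fits = fits, r2 = r2, param_matrix = pm)
}

#' Run the full pipeline
#'
#' simulate (optional) -> fit -> analyze.  Every stage writes its outputs and
#' a JSON manifest under `out_dir`; any stage error leaves partial outputs in
#' place together with a `FAILED` marker file and re-raises the error.
#'
#' @param cfg a [run_config()].
#' @return list with `cohort`, `fit` (see [fit_cohort()]), `analysis` (see
#'   [analyze_parameters()]), and `out_dir`, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (cfg$verbose) message(...)
  tryCatch({
    # --- stage 1: cohort -------------------------------------------------
    if (is.null(cfg$cohort_dir)) {
      say("simulate: generating synthetic cohort")
      cc <- cfg$cohort
      cc$seed <- split_seed(cfg$seed, "simulate")
      cohort <- gen_cohort(cc)
      cohort_dir <- file.path(cfg$out_dir, "cohort")
      write_cohort(cohort, cohort_dir)
      data <- list(template = cohort$template, connectome = cohort$connectome,
                   subjects = cohort$subjects, cognitive = cohort$cognitive)
    } else {
      say("loading cohort from ", cfg$cohort_dir)
      data <- read_cohort(cfg$cohort_dir)
    }

    # --- stage 2: per-subject fits --------------------------------------
    say("fit: ", length(data$subjects), " subjects")
    hs <- cfg$horseshoe
    hs$seed <- split_seed(cfg$seed, "fit")
    fit <- fit_cohort(data$subjects, data$template, data$connectome, hs,
                      verbose = cfg$verbose)
    fit_dir <- file.path(cfg$out_dir, "fit")
    dir.create(fit_dir, showWarnings = FALSE)
    write_matrix(fit$param_matrix, file.path(fit_dir, "gene_params.tsv"), "subject")
    write_matrix(fit$r2, file.path(fit_dir, "r2.tsv"), "subject")
    write_manifest(file.path(fit_dir, "manifest.json"), stage = "fit",
                   n_burn = hs$n_burn, n_keep = hs$n_keep, seed = cfg$seed,
                   sampler_mode = hs$sampler_mode)

    # --- stage 3: population analysis -----------------------------------
    say("analyze: stability filter + PLS + permutation + bootstrap")
    slopes <- cognitive_slopes(data$cognitive)
    slopes <- slopes[rownames(fit$param_matrix), , drop = FALSE]
    analysis <- analyze_parameters(fit$param_matrix, slopes,
                                   ci_level = cfg$ci_level,
                                   n_perm = cfg$n_perm, n_boot = cfg$n_boot,
                                   threshold = cfg$threshold,
                                   seed = split_seed(cfg$seed, "analyze"))
    an_dir <- file.path(cfg$out_dir, "analysis")
    dir.create(an_dir, showWarnings = FALSE)
    write_matrix(cbind(explained_variance = analysis$explained_variance,
                       p_value = analysis$component_pvalues),
                 file.path(an_dir, "components.tsv"), "component")
    write_matrix(analysis$saliences, file.path(an_dir, "saliences.tsv"), "parameter")
    write_matrix(analysis$score_loadings,
                 file.path(an_dir, "score_loadings.tsv"), "score")
    if (!is.null(analysis$bootstrap))
      write_matrix(cbind(salience = analysis$bootstrap$salience,
                         se = analysis$bootstrap$se,
                         ratio = analysis$bootstrap$ratios),
                   file.path(an_dir, "bootstrap_ratios.tsv"), "parameter")
    gt <- analysis$gene_table
    writeLines(c(paste(names(gt), collapse = "\t"),
                 if (nrow(gt)) paste(gt$gene, gt$source_factor, gt$target_factor,
                                     fmt_num(gt$salience), fmt_num(gt$ratio),
                                     sep = "\t")),
               file.path(an_dir, "selected_genes.tsv"))
    write_manifest(file.path(an_dir, "manifest.json"), stage = "analyze",
                   ci_level = cfg$ci_level, n_perm = cfg$n_perm,
                   n_boot = cfg$n_boot, threshold = cfg$threshold,
                   seed = cfg$seed,
                   n_stable = length(analysis$stable_param_indices),
                   n_selected = nrow(gt))
    say("done: outputs in ", cfg$out_dir)
    invisible(list(cohort = if (is.null(cfg$cohort_dir)) cohort else NULL,
                   fit = fit, analysis = analysis, out_dir = cfg$out_dir))
  }, error = function(e) {
    writeLines(c("pipeline failed:", conditionMessage(e)),
               file.path(cfg$out_dir, "FAILED"))
    stop(e)
  })
}
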