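#' Population-level analysis
#'
#' Links per-subject model parameters to cognitive decline: parameters stable
#' across the population (99% CI excluding zero) enter a behavioural
#' partial-least-squares analysis — SVD of the cross-block correlation matrix
#' between parameters and cognitive slopes — with permutation tests for
#' component significance and bootstrap ratios for the reliability of
#' individual parameter saliences.
#'
#' @name population_analysis
NULL

#' Across-population stability filter
#'
#' Keeps parameters whose t-based confidence interval of the across-subject
#' mean excludes zero at `ci_level`.  A parameter with zero across-subject
#' variance is kept when its (common) value is nonzero — its CI is a point —
#' and dropped when zero.
#'
#' @param params numeric matrix subjects x parameters.
#' @param ci_level confidence level (default 0.99).
#' @return integer vector of retained column indices (named when `params`
#'   has column names).
#' @export
stability_filter <- function(params, ci_level = 0.99) {
  params <- as.matrix(params)
  ci_level <- check_scalar(ci_level, "ci_level", 0, 1, TRUE, TRUE)
  n <- nrow(params)
  if (n < 3L) stop_invalid("at least 3 subjects required")
  mu <- colMeans(params)
  se <- apply(params, 2L, sd) / sqrt(n)
  crit <- qt(1 - (1 - ci_level) / 2, df = n - 1L)
  lo <- mu - crit * se
  hi <- mu + crit * se
  keep <- (lo > 0 | hi < 0) | (se == 0 & mu != 0)
  idx <- which(keep)
  if (!is.null(colnames(params))) names(idx) <- colnames(params)[idx]
  idx
}

drop_zero_variance <- function(mat, block) {
  v <- apply(mat, 2L, sd)
  bad <- which(v == 0 | !is.finite(v))
  if (length(bad)) {
    warning("excluding ", length(bad), " zero-variance column(s) from the ",
            block, " block")
    mat <- mat[, -bad, drop = FALSE]
  }
  list(mat = mat, kept = setdiff(seq_len(length(v)), bad))
}

#' Behavioural PLS via SVD of the cross-block correlation matrix
#'
#' Both blocks are z-scored column-wise; the `p x q` cross-correlation matrix
#' `R = cor(params, slopes)` is decomposed as `R = U S V'`.  Columns of `U`
#' are parameter saliences, columns of `V` cognitive-score loadings; the
#' explained-variance fraction of component `i` is `s_i^2 / sum(s^2)`.  Each
#' component is oriented so that the cognitive score with the largest
#' absolute loading has a positive loading.
#'
#' @param params numeric matrix subjects x parameters (e.g. the stable
#'   columns of [stack_gene_params()]).
#' @param slopes numeric matrix subjects x scores (see [cognitive_slopes()]);
#'   subjects with undefined slopes must be excluded upstream.
#' @return a `pls_result` list: `singular_values`, `explained_variance`,
#'   `saliences` (parameters x components), `score_loadings` (scores x
#'   components), `param_kept`, `score_kept` (column indices surviving the
#'   zero-variance screen).
#' @export
svd_pls <- function(params, slopes) {
  params <- as.matrix(params); slopes <- as.matrix(slopes)
  if (nrow(params) != nrow(slopes)) stop_invalid("subject counts differ between blocks")
  if (anyNA(params) || anyNA(slopes))
    stop_invalid("missing values are not allowed; exclude incomplete subjects upstream")
  px <- drop_zero_variance(params, "parameter")
  sx <- drop_zero_variance(slopes, "slope")
  if (ncol(px$mat) == 0L || ncol(sx$mat) == 0L)
    stop_invalid("a block has no non-constant columns")
  R <- cor(px$mat, sx$mat)
  sv <- svd(R)
  U <- sv$u; V <- sv$v; d <- sv$d
  for (ci in seq_along(d)) {        # sign convention per component
    j <- which.max(abs(V[, ci]))
    if (V[j, ci] < 0) { V[, ci] <- -V[, ci]; U[, ci] <- -U[, ci] }
  }
  rownames(U) <- colnames(px$mat)
  rownames(V) <- colnames(sx$mat)
  structure(list(singular_values = d,
                 explained_variance = d^2 / sum(d^2),
                 saliences = U, score_loadings = V,
                 param_kept = px$kept, score_kept = sx$kept),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat("<pls_result> ", length(x$singular_values), " components; explained variance: ",
      paste(signif(100 * x$explained_variance, 3), collapse = "% "), "%\n", sep = "")
  if (!is.null(x$component_pvalues))
    cat("  permutation p-values: ",
        paste(signif(x$component_pvalues, 3), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Permutation test for PLS component significance
#'
#' Rows of the cognitive block are permuted; singular values are recomputed
#' per permutation and compared with the observed ones.  P-values use the
#' add-one estimator `p_i = (1 + #{s_perm >= s_obs}) / (n_perm + 1)`, so they
#' are never zero.
#'
#' @param params,slopes as in [svd_pls()].
#' @param n_perm number of permutations (>= 1; 10000 for confirmatory use).
#' @param seed integer seed.
#' @return numeric vector of per-component p-values.
#' @export
permutation_component_test <- function(params, slopes, n_perm = 10000L, seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm")
  obs <- svd_pls(params, slopes)
  d_obs <- obs$singular_values
  slopes <- as.matrix(slopes)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(check_count(seed, "seed", min = 0L))
  count <- numeric(length(d_obs))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(nrow(slopes))
    d_b <- suppressWarnings(
      svd_pls(params, slopes[perm, , drop = FALSE])$singular_values)
    len <- min(length(d_b), length(d_obs))
    count[seq_len(len)] <- count[seq_len(len)] +
      (d_b[seq_len(len)] >= d_obs[seq_len(len)])
  }
  (1 + count) / (n_perm + 1)
}

procrustes_rotation <- function(Vb, V) {
  sv <- svd(crossprod(Vb, V))
  sv$u %*% t(sv$v)
}

#' Bootstrap ratios of parameter saliences
#'
#' Subjects are resampled with replacement; the PLS is recomputed on each
#' bootstrap sample and the bootstrap salience matrix is aligned to the
#' original by an orthogonal Procrustes rotation of the score-loading block
#' (or a simple per-component sign flip with `align = "sign"`).  The
#' bootstrap ratio of parameter `j` is its original salience divided by its
#' bootstrap standard error; parameters with `|ratio| > threshold` are
#' selected.  Variability is measured on the singular-value-weighted
#' saliences (`U S`, the cross-correlation scale): unit-norm saliences are
#' unsuitable for the SE because resampling noise inflates the norm of the
#' bootstrap cross-correlation matrix when many parameters are carried,
#' which would shrink the SE and make the ratios anticonservative.  Draws in
#' which a retained column loses all variance are redrawn (count reported).
#'
#' @param params,slopes as in [svd_pls()].
#' @param component component index tested (default 1).
#' @param n_boot number of bootstrap draws (>= 2; 10000 for confirmatory
#'   use).
#' @param seed integer seed.
#' @param threshold selection threshold on |ratio| (default 2.58,
#'   approximately a 99% normal z-score).
#' @param align `"procrustes"` (default) or `"sign"`.
#' @return list: `ratios` (named, original salience / bootstrap SE),
#'   `selected` (labels with |ratio| > threshold), `salience`, `se`,
#'   `infinite` (labels with SE = 0, reported separately), `n_redraws`.
#' @export
bootstrap_ratios <- function(params, slopes, component = 1L, n_boot = 10000L,
                             seed = 1L, threshold = 2.58,
                             align = c("procrustes", "sign")) {
  n_boot <- check_count(n_boot, "n_boot", min = 2L)
  align <- match.arg(align)
  params <- as.matrix(params); slopes <- as.matrix(slopes)
  obs <- svd_pls(params, slopes)
  component <- check_count(component, "component")
  if (component > length(obs$singular_values))
    stop_invalid("component ", component, " does not exist")
  pk <- obs$param_kept; sk <- obs$score_kept
  P <- params[, pk, drop = FALSE]; Q <- slopes[, sk, drop = FALSE]
  n <- nrow(P)
  n_comp <- length(obs$singular_values)
  boot_sal <- matrix(NA_real_, n_boot, nrow(obs$saliences))
  n_redraws <- 0L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(check_count(seed, "seed", min = 0L))
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      Pb <- P[idx, , drop = FALSE]; Qb <- Q[idx, , drop = FALSE]
      ok <- all(apply(Pb, 2L, sd) > 0) && all(apply(Qb, 2L, sd) > 0)
      if (ok) break
      n_redraws <- n_redraws + 1L
    }
    Rb <- cor(scale(Pb), scale(Qb))
    svb <- svd(Rb)
    # singular-value-weighted saliences: rows of U S live on the scale of Rb
    Ub <- sweep(svb$u[, seq_len(n_comp), drop = FALSE], 2L,
                svb$d[seq_len(n_comp)], "*")
    Vb <- svb$v[, seq_len(n_comp), drop = FALSE]
    if (align == "procrustes") {
      Qrot <- procrustes_rotation(Vb, obs$score_loadings)
      Ub <- Ub %*% Qrot
    } else {
      flips <- sign(colSums(Vb * obs$score_loadings))
      flips[flips == 0] <- 1
      Ub <- sweep(Ub, 2L, flips, "*")
    }
    boot_sal[b, ] <- Ub[, component]
  }
  se <- apply(boot_sal, 2L, sd)
  sal <- obs$saliences[, component]
  sal_w <- sal * obs$singular_values[component]
  ratios <- ifelse(se > 0, sal_w / se, Inf * sign(sal_w))
  names(ratios) <- rownames(obs$saliences)
  infinite <- names(ratios)[se == 0]
  finite_sel <- names(ratios)[se > 0 & abs(ratios) > threshold]
  list(ratios = ratios, selected = finite_sel,
       salience = setNames(sal, names(ratios)), se = setNames(se, names(ratios)),
       infinite = infinite, n_redraws = n_redraws, component = component)
}

#' Tabulate selected gene-imaging parameters
#'
#' Parses parameter labels of the form `gene:source->target` (as produced by
#' [param_labels()] / [stack_gene_params()]) into a ranked table.  Rows are
#' sorted by decreasing |salience|, ties broken by label order; a gene may
#' appear in several interaction rows.
#'
#' @param selected character vector of selected parameter labels.
#' @param salience named numeric vector of saliences (superset of
#'   `selected`).
#' @param ratios named numeric vector of bootstrap ratios.
#' @return data.frame with columns gene, source_factor, target_factor,
#'   salience, ratio.
#' @export
rank_genes <- function(selected, salience, ratios) {
  if (length(selected) == 0L)
    return(data.frame(gene = character(0), source_factor = character(0),
                      target_factor = character(0), salience = numeric(0),
                      ratio = numeric(0), stringsAsFactors = FALSE))
  parts <- regmatches(selected, regexec("^(.*):(.*)->(.*)$", selected))
  bad <- vapply(parts, length, integer(1)) != 4L
  if (any(bad)) stop_invalid("unparseable parameter label(s): ",
                             paste(selected[bad], collapse = ", "))
  out <- data.frame(
    gene = vapply(parts, `[`, character(1), 2L),
    source_factor = vapply(parts, `[`, character(1), 3L),
    target_factor = vapply(parts, `[`, character(1), 4L),
    salience = unname(salience[selected]),
    ratio = unname(ratios[selected]),
    stringsAsFactors = FALSE)
  ord <- order(-abs(out$salience), selected)
  out[ord, , drop = FALSE]
}

#' Full population pipeline
#'
#' Stability filter, behavioural PLS, permutation test, and — for the first
#' component with permutation p below `p_threshold` — bootstrap ratios and
#' the ranked gene table.
#'
#' @param params subjects x parameters matrix (e.g. [stack_gene_params()]).
#' @param slopes subjects x scores matrix.
#' @param ci_level stability-filter confidence level (default 0.99).
#' @param n_perm,n_boot resampling sizes (defaults 10000).
#' @param threshold bootstrap-ratio selection threshold (default 2.58).
#' @param p_threshold component significance level (default 0.05).
#' @param seed integer seed, fanned out to the permutation and bootstrap
#'   stages.
#' @return a `pls_result` augmented with `stable_param_indices`,
#'   `component_pvalues`, `bootstrap` (from [bootstrap_ratios()], or `NULL`
#'   when no component is significant), and `gene_table`.
#' @export
analyze_parameters <- function(params, slopes, ci_level = 0.99,
                               n_perm = 10000L, n_boot = 10000L,
                               threshold = 2.58, p_threshold = 0.05,
                               seed = 1L) {
  params <- as.matrix(params); slopes <- as.matrix(slopes)
  complete <- complete.cases(slopes) & complete.cases(params)
  if (!all(complete)) {
    message("excluding ", sum(!complete), " subject(s) with undefined slopes")
    params <- params[complete, , drop = FALSE]
    slopes <- slopes[complete, , drop = FALSE]
  }
  stable <- stability_filter(params, ci_level)
  if (length(stable) == 0L) stop_invalid("no parameter passed the stability filter")
  P <- params[, stable, drop = FALSE]
  res <- svd_pls(P, slopes)
  res$stable_param_indices <- stable
  res$component_pvalues <- permutation_component_test(
    P, slopes, n_perm, seed = split_seed(seed, "permutation"))
  sig <- which(res$component_pvalues < p_threshold)
  if (length(sig)) {
    res$bootstrap <- bootstrap_ratios(P, slopes, component = sig[1L],
                                      n_boot = n_boot,
                                      seed = split_seed(seed, "bootstrap"),
                                      threshold = threshold)
    res$gene_table <- rank_genes(res$bootstrap$selected,
                                 res$bootstrap$salience, res$bootstrap$ratios)
  } else {
    res$bootstrap <- NULL
    res$gene_table <- rank_genes(character(0), numeric(0), numeric(0))
  }
  res
}
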