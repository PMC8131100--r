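#' Multifactorial causal model core
#'
#' The model treats each brain region as carrying several macroscopic
#' biological factors (e.g. amyloid-beta, tau, cerebral blood flow, glucose
#' metabolism, resting functional activity, grey-matter density).  The rate of
#' change of factor `m` in region `i` is
#'
#' \deqn{dS_i^m/dt = \sum_n \big(\alpha_0^{n\to m} + \sum_k \alpha_k^{n\to m}
#'   G_i^k\big) S_i^n \;+\; \beta^m \sum_{j\ne i} C_{ji} (S_j^m - S_i^m)}
#'
#' where `G` is the (z-scored) regional gene-expression template, `C` a
#' nonnegative anatomical connectome with zero diagonal, and `beta^m` a single
#' scalar spreading coefficient per factor.  With `n_genes` genes and
#' `n_factors` factors the parameter vector for one target factor has length
#' `n_factors + n_genes * n_factors + 1` (5863 for 976 genes and 6 factors).
#'
#' @name mcm_core
NULL

#' Construct a subject timeseries
#'
#' @param values numeric array `n_factors x n_rois x n_times` of regional
#'   factor values in normalized imaging units.
#' @param times numeric vector of acquisition times in years, strictly
#'   increasing, one per time point.
#' @param factor_names optional character vector of factor names.
#' @param region_ids optional character vector of region identifiers.
#' @return an object of class `subject_timeseries`.
#' @export
subject_timeseries <- function(values, times, factor_names = NULL, region_ids = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_invalid("values must be a 3-d array (factors x regions x times)")
  d <- dim(values)
  if (length(times) != d[3L]) stop_invalid("length(times) must equal dim(values)[3]")
  if (d[3L] >= 2L && any(diff(times) <= 0)) stop_invalid("times must be strictly increasing")
  if (!all(is.finite(values))) stop_invalid("values must be finite")
  factor_names <- factor_names %||% paste0("F", seq_len(d[1L]))
  region_ids <- region_ids %||% paste0("R", seq_len(d[2L]))
  if (length(factor_names) != d[1L] || length(region_ids) != d[2L])
    stop_invalid("factor_names/region_ids lengths must match the value array")
  structure(list(values = values, times = as.numeric(times),
                 factor_names = as.character(factor_names),
                 region_ids = as.character(region_ids)),
            class = "subject_timeseries")
}

#' @export
print.subject_timeseries <- function(x, ...) {
  d <- dim(x$values)
  cat("<subject_timeseries> ", d[1L], " factors x ", d[2L], " regions x ",
      d[3L], " time points (", format(min(x$times)), "-", format(max(x$times)),
      " y)\n", sep = "")
  invisible(x)
}

#' Construct a per-target-factor parameter set
#'
#' Holds the regression coefficients of the model for one target factor `m`:
#' `n_factors` baseline interaction terms, an `n_genes x n_factors` matrix of
#' gene-modulation terms, and one spreading coefficient.
#'
#' @param alpha0 numeric vector of length `n_factors`: baseline factor-to-factor
#'   interaction coefficients (source factor n -> target m).
#' @param alpha_gene numeric matrix `n_genes x n_factors`: gene k modulation of
#'   the influence of source factor n on the target factor.
#' @param beta_spread single numeric: coefficient of the connectome spreading
#'   term.
#' @param target_factor identifier (name or index) of the target factor.
#' @return an object of class `factor_params`.
#' @export
factor_params <- function(alpha0, alpha_gene, beta_spread, target_factor = NA) {
  alpha_gene <- as.matrix(alpha_gene)
  if (ncol(alpha_gene) > 0 && length(alpha0) != ncol(alpha_gene))
    stop_invalid("length(alpha0) must equal ncol(alpha_gene)")
  check_scalar(beta_spread, "beta_spread")
  structure(list(alpha0 = as.numeric(alpha0), alpha_gene = alpha_gene,
                 beta_spread = as.numeric(beta_spread),
                 target_factor = target_factor),
            class = "factor_params")
}

#' Flatten a parameter set into the design-matrix column order
#'
#' Column order (documented and stable): the `n_factors` baseline terms first
#' (source factors in order), then the gene block gene-major — all source
#' factors for gene 1, then gene 2, ... — then the single spreading
#' coefficient.  The flattened length is `n_factors + n_genes*n_factors + 1`.
#'
#' @param p a `factor_params` object.
#' @return numeric vector.
#' @export
flatten_params <- function(p) {
  stopifnot(inherits(p, "factor_params"))
  c(p$alpha0, as.vector(t(p$alpha_gene)), p$beta_spread)
}

#' Inverse of [flatten_params()]
#'
#' @param theta numeric vector of length `n_factors + n_genes*n_factors + 1`.
#' @param n_genes number of genes.
#' @param n_factors number of factors.
#' @param target_factor passed through to [factor_params()].
#' @return a `factor_params` object.
#' @export
unflatten_params <- function(theta, n_genes, n_factors, target_factor = NA) {
  n_genes <- check_count(n_genes, "n_genes", min = 0L)
  n_factors <- check_count(n_factors, "n_factors")
  expected <- n_factors + n_genes * n_factors + 1L
  if (length(theta) != expected)
    stop_invalid("theta has length ", length(theta), ", expected ", expected)
  alpha0 <- theta[seq_len(n_factors)]
  gene_block <- theta[n_factors + seq_len(n_genes * n_factors)]
  alpha_gene <- matrix(gene_block, nrow = n_genes, ncol = n_factors, byrow = TRUE)
  factor_params(alpha0, alpha_gene, theta[length(theta)], target_factor)
}

#' Names of the flattened parameter vector
#'
#' @param gene_ids character vector of gene identifiers.
#' @param factor_names character vector of factor names (source factors).
#' @param target_factor target factor name, used as suffix.
#' @return character vector labelling each flattened coefficient.
#' @export
param_labels <- function(gene_ids, factor_names, target_factor) {
  base <- paste0("alpha0:", factor_names, "->", target_factor)
  if (length(gene_ids)) {
    grid <- expand.grid(src = factor_names, gene = gene_ids,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    gene <- paste0(grid$gene, ":", grid$src, "->", target_factor)
  } else gene <- character(0)
  c(base, gene, paste0("spread->", target_factor))
}

resolve_factor <- function(ts, factor) {
  if (is.character(factor)) {
    m <- match(factor, ts$factor_names)
    if (is.na(m)) stop_invalid("unknown factor '", factor, "'")
    return(m)
  }
  check_count(factor, "factor")
}

#' Finite-difference derivatives of one factor
#'
#' Computes `(S(t+1) - S(t)) / (time(t+1) - time(t))` per region for each pair
#' of consecutive time points and concatenates them time-major (all regions of
#' interval 1, then interval 2, ...), yielding `n_rois * (n_times - 1)` values.
#' Derivatives are annualized rates (per year) since times are in years.
#'
#' @param ts a [subject_timeseries()].
#' @param factor target factor name or index.
#' @return numeric vector of length `n_rois * (n_times - 1)` with attribute
#'   `left_index`: for each entry, the index of the interval's left time point
#'   (where predictors are evaluated).
#' @export
finite_difference_derivatives <- function(ts, factor) {
  stopifnot(inherits(ts, "subject_timeseries"))
  m <- resolve_factor(ts, factor)
  d <- dim(ts$values)
  if (d[3L] < 2L) stop_invalid("at least 2 time points are required")
  S <- ts$values[m, , , drop = TRUE]            # regions x times
  S <- matrix(S, nrow = d[2L], ncol = d[3L])
  dt <- diff(ts$times)
  dS <- (S[, -1L, drop = FALSE] - S[, -d[3L], drop = FALSE]) /
    rep(dt, each = d[2L])
  out <- as.vector(dS)                          # time-major: interval-by-interval
  attr(out, "left_index") <- rep(seq_len(d[3L] - 1L), each = d[2L])
  out
}

check_connectome <- function(conn, n_rois = NULL) {
  conn <- as.matrix(conn)
  if (nrow(conn) != ncol(conn)) stop_invalid("connectome must be square")
  if (!all(is.finite(conn))) stop_invalid("connectome must be finite")
  if (any(conn < 0)) stop_invalid("connectome must be nonnegative")
  if (any(diag(conn) != 0)) stop_invalid("connectome diagonal must be zero")
  if (!is.null(n_rois) && nrow(conn) != n_rois)
    stop_invalid("connectome has ", nrow(conn), " regions, expected ", n_rois)
  conn
}

align_template <- function(template, ts) {
  stopifnot(inherits(template, "gene_template"))
  if (!identical(template$region_ids, ts$region_ids)) {
    m <- match(ts$region_ids, template$region_ids)
    if (anyNA(m))
      stop_invalid("region ids missing from template: ",
                   paste(ts$region_ids[is.na(m)], collapse = ", "))
    template$matrix <- template$matrix[, m, drop = FALSE]
    template$region_ids <- ts$region_ids
  }
  template
}

# Spreading predictor for the state s (length n_rois) of the target factor:
# sum_{j != i} C[j, i] * (s[j] - s[i]).
spreading_term <- function(conn, s) {
  as.vector(crossprod(conn, s)) - s * colSums(conn)
}

#' Build the per-subject regression design matrix
#'
#' Linearizes model fitting: each row corresponds to one (region, time
#' interval) derivative observation; columns follow the order documented in
#' [flatten_params()].  Predictors are evaluated at the left endpoint of each
#' interval (explicit-Euler convention), so trajectories generated by
#' forward-Euler at the observation times satisfy
#' `finite_difference_derivatives == design %*% flatten_params` exactly.
#'
#' @param ts a [subject_timeseries()].
#' @param template a [gene_template()] aligned (or alignable by region id) to
#'   `ts`.
#' @param conn connectome matrix (`n_rois x n_rois`, nonnegative, zero
#'   diagonal).
#' @param target_factor target factor name or index.
#' @return numeric matrix `n_rois*(n_times-1) x (n_factors +
#'   n_genes*n_factors + 1)` with column names from [param_labels()].
#' @export
build_design_matrix <- function(ts, template, conn, target_factor) {
  stopifnot(inherits(ts, "subject_timeseries"))
  template <- align_template(template, ts)
  d <- dim(ts$values)
  n_factors <- d[1L]; n_rois <- d[2L]; n_times <- d[3L]
  if (n_times < 2L) stop_invalid("at least 2 time points are required")
  conn <- check_connectome(conn, n_rois)
  m <- resolve_factor(ts, target_factor)
  G <- template$matrix                          # genes x regions
  n_genes <- nrow(G)
  Gt <- t(G)                                    # regions x genes

  p <- n_factors + n_genes * n_factors + 1L
  X <- matrix(0, nrow = n_rois * (n_times - 1L), ncol = p)
  gene_cols <- if (n_genes > 0)
    n_factors + seq_len(n_genes * n_factors) else integer(0)
  # gene-major column layout: column (k, n) sits at n_factors + (k-1)*n_factors + n
  k_of_col <- rep(seq_len(n_genes), each = n_factors)
  n_of_col <- rep(seq_len(n_factors), times = n_genes)

  for (tt in seq_len(n_times - 1L)) {
    rows <- (tt - 1L) * n_rois + seq_len(n_rois)
    St <- matrix(ts$values[, , tt], nrow = n_factors, ncol = n_rois)
    Srt <- t(St)                                # regions x factors
    X[rows, seq_len(n_factors)] <- Srt
    if (n_genes > 0)
      X[rows, gene_cols] <- Gt[, k_of_col, drop = FALSE] *
        Srt[, n_of_col, drop = FALSE]
    X[rows, p] <- spreading_term(conn, St[m, ])
  }
  colnames(X) <- param_labels(template$gene_ids, ts$factor_names,
                              ts$factor_names[m])
  X
}

#' Simulate the forward model
#'
#' Forward-Euler integration of the model dynamics at the supplied observation
#' times.  By default one Euler step spans each inter-observation interval, so
#' the inverse problem (fit from finite differences) is exactly linear; set
#' `n_substeps > 1` for a finer integration grid to probe discretization
#' robustness.
#'
#' @param params list of `n_factors` [factor_params()] objects, one per target
#'   factor, in factor order.
#' @param s0 numeric matrix `n_factors x n_rois` of initial states.
#' @param times numeric vector of observation times (years), strictly
#'   increasing.
#' @param template a [gene_template()].
#' @param conn connectome matrix.
#' @param n_substeps integer >= 1: Euler sub-steps per observation interval.
#' @param magnitude_bound abort if any |state| exceeds this bound
#'   (`simulation-unstable` error naming the step).
#' @param factor_names,region_ids optional labels for the returned timeseries.
#' @return a [subject_timeseries()] of the simulated trajectory.
#' @export
simulate_forward <- function(params, s0, times, template, conn,
                             n_substeps = 1L, magnitude_bound = 1e6,
                             factor_names = NULL, region_ids = NULL) {
  s0 <- as.matrix(s0)
  n_factors <- nrow(s0); n_rois <- ncol(s0)
  if (length(params) != n_factors)
    stop_invalid("need one factor_params per factor (", n_factors, ")")
  if (length(times) < 1L || (length(times) > 1L && any(diff(times) <= 0)))
    stop_invalid("times must be strictly increasing")
  conn <- check_connectome(conn, n_rois)
  n_substeps <- check_count(n_substeps, "n_substeps")
  G <- template$matrix
  if (ncol(G) != n_rois) stop_invalid("template regions do not match s0")

  # Effective per-region interaction weights: W[[m]] is regions x factors with
  # W[i, n] = alpha0[n] + sum_k alpha_gene[k, n] * G[k, i].
  W <- lapply(params, function(p) {
    stopifnot(inherits(p, "factor_params"))
    base <- matrix(p$alpha0, nrow = n_rois, ncol = n_factors, byrow = TRUE)
    if (nrow(p$alpha_gene) > 0) base <- base + crossprod(G, p$alpha_gene)
    base
  })
  beta <- vapply(params, function(p) p$beta_spread, numeric(1))

  deriv <- function(S) {
    Srt <- t(S)
    out <- matrix(0, n_factors, n_rois)
    for (mm in seq_len(n_factors)) {
      out[mm, ] <- rowSums(W[[mm]] * Srt) + beta[mm] * spreading_term(conn, S[mm, ])
    }
    out
  }

  n_times <- length(times)
  values <- array(0, dim = c(n_factors, n_rois, n_times))
  values[, , 1L] <- s0
  S <- s0
  if (n_times > 1L) for (tt in seq_len(n_times - 1L)) {
    h <- (times[tt + 1L] - times[tt]) / n_substeps
    for (ss in seq_len(n_substeps)) {
      S <- S + h * deriv(S)
      if (any(!is.finite(S)) || max(abs(S)) > magnitude_bound)
        stop(errorCondition(
          paste0("simulation unstable at observation interval ", tt,
                 ", sub-step ", ss, ": |state| exceeded ", magnitude_bound),
          class = c("gemcm_simulation_unstable", "error")))
    }
    values[, , tt + 1L] <- S
  }
  subject_timeseries(values, times, factor_names, region_ids)
}

#' Coefficient of determination of predicted derivatives
#'
#' `1 - SS_res / SS_tot` with `SS_tot` about the observed mean.  Returns `NA`
#' (with a warning) when the observed derivatives have zero variance, where
#' the statistic is undefined.
#'
#' @param observed numeric vector of observed derivative values.
#' @param predicted numeric vector of model-predicted derivative values.
#' @return single numeric R-squared, or `NA_real_` if undefined.
#' @export
r2_score <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L)
    stop_invalid("observed and predicted must have equal length >= 2")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    warning("observed derivatives have zero variance; R2 undefined")
    return(NA_real_)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}
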