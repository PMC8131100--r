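#' Cohort screening and derived quantities
#'
#' Baseline screening and per-subject derived measures: multivariate outlier
#' detection by Mahalanobis distance against a chi-square threshold,
#' imputation of missing modalities by trimmed-scores regression with an
#' internal PCA, and per-subject cognitive slopes from longitudinal score
#' tables.
#'
#' @name preprocess
NULL

#' Mahalanobis multivariate outlier screen
#'
#' A subject is flagged as an outlier when its squared Mahalanobis distance to
#' the sample mean exceeds the upper-`alpha` quantile of the chi-square
#' distribution with `ncol(data)` degrees of freedom (significant squared
#' distance at level `alpha`).  A numerically singular covariance is
#' ridge-regularized (with a message); if still singular the data are
#' degenerate and an error is raised.
#'
#' @param data numeric matrix, subjects in rows, features in columns; more
#'   subjects than features required.
#' @param alpha significance level (default 0.05).
#' @return logical vector, `TRUE` marks outliers; attribute `d2` carries the
#'   squared distances.
#' @export
mahalanobis_outliers <- function(data, alpha = 0.05) {
  data <- as.matrix(data)
  alpha <- check_scalar(alpha, "alpha", 0, 1, TRUE, TRUE)
  n <- nrow(data); k <- ncol(data)
  if (n <= k) stop_invalid("need more subjects (", n, ") than features (", k, ")")
  if (!all(is.finite(data))) stop_invalid("data must be finite")
  mu <- colMeans(data)
  S <- cov(data)
  d2 <- tryCatch(mahalanobis(data, mu, S), error = function(e) NULL)
  if (is.null(d2)) {
    ridge <- 1e-8 * mean(diag(S))
    if (!is.finite(ridge) || ridge <= 0)
      stop(errorCondition("degenerate data: covariance is singular and not regularizable",
                          class = c("gemcm_degenerate_data", "error")))
    message("singular covariance: applying ridge regularization")
    d2 <- tryCatch(mahalanobis(data, mu, S + diag(ridge, k)),
                   error = function(e)
                     stop(errorCondition("degenerate data: covariance singular after regularization",
                                         class = c("gemcm_degenerate_data", "error"))))
  }
  out <- d2 > qchisq(1 - alpha, df = k)
  attr(out, "d2") <- d2
  out
}

#' Trimmed-scores regression imputation with internal PCA
#'
#' Iterative low-rank imputation: missing entries are initialized at column
#' means; at each iteration a rank-`n_components` PCA of the completed matrix
#' is fitted, scores for each incomplete row are regressed from its observed
#' features (trimmed scores), and the missing features are reconstructed from
#' those scores.  Iteration stops when the relative change of the imputed
#' values drops below `tol`.
#'
#' @param data numeric matrix with `NA` marking missing entries; every row
#'   must retain at least one observed feature.
#' @param n_components PCA rank; if `NULL`, the smallest rank explaining
#'   `var_explained` of the variance of the initial completion is used.
#' @param var_explained explained-variance threshold used when `n_components`
#'   is `NULL` (default 0.9).
#' @param tol relative-change convergence tolerance (default 1e-8).
#' @param max_iter iteration cap; non-convergence returns the best iterate
#'   with a warning and `converged = FALSE`.
#' @return the completed matrix; attributes `converged`, `iterations`,
#'   `history` (relative change per iteration).
#' @export
tsr_impute <- function(data, n_components = NULL, var_explained = 0.9,
                       tol = 1e-8, max_iter = 200L) {
  X <- as.matrix(data)
  miss <- is.na(X)
  if (!any(miss)) {
    attr(X, "converged") <- TRUE
    attr(X, "iterations") <- 0L
    attr(X, "history") <- numeric(0)
    return(X)
  }
  if (any(rowSums(!miss) == 0L))
    stop_invalid("rows with no observed feature cannot be imputed: row(s) ",
                 paste(which(rowSums(!miss) == 0L), collapse = ", "))
  n <- nrow(X); k <- ncol(X)
  col_mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(k)) X[miss[, j], j] <- col_mu[j]

  if (is.null(n_components)) {
    sv <- svd(scale(X, scale = FALSE))$d^2
    n_components <- max(1L, min(which(cumsum(sv) / sum(sv) >= var_explained)))
  }
  n_components <- check_count(n_components, "n_components")
  if (n_components >= min(n, k))
    stop_invalid("n_components must be < min(subjects, features)")

  history <- numeric(0)
  converged <- FALSE
  it <- 0L
  incomplete <- which(rowSums(miss) > 0L)
  while (it < max_iter) {
    it <- it + 1L
    mu <- colMeans(X)
    Xc <- sweep(X, 2L, mu)
    sv <- svd(Xc, nu = 0L, nv = n_components)
    P <- sv$v                                  # features x r loadings
    old <- X[miss]
    for (i in incomplete) {
      obs <- !miss[i, ]
      Po <- P[obs, , drop = FALSE]
      # trimmed scores: least-squares scores from the observed block only
      t_i <- qr.coef(qr(Po), Xc[i, obs])
      t_i[is.na(t_i)] <- 0
      X[i, !obs] <- mu[!obs] + P[!obs, , drop = FALSE] %*% t_i
    }
    rel <- sqrt(sum((X[miss] - old)^2)) / max(sqrt(sum(old^2)), .Machine$double.eps)
    history <- c(history, rel)
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("tsr_impute did not converge in ", max_iter,
            " iterations (last relative change ", signif(rel, 3), ")")
  attr(X, "converged") <- converged
  attr(X, "iterations") <- it
  attr(X, "history") <- history
  X
}

#' Per-subject cognitive slopes
#'
#' Ordinary least-squares slope of each score against age, per subject.
#' Subjects with fewer than two non-missing visits for a score get `NA` for
#' that slope (undefined, never zero-filled).
#'
#' @param table long-format data.frame with columns `subject_id`, `age`
#'   (years), `score_name`, `value` (missing values allowed as `NA`).
#' @param score_names optional explicit score order for the output columns.
#' @return numeric matrix subjects x scores of slopes (score points per year),
#'   rownames = subject ids.
#' @export
cognitive_slopes <- function(table, score_names = NULL) {
  need <- c("subject_id", "age", "score_name", "value")
  if (!all(need %in% names(table)))
    stop_invalid("table must have columns ", paste(need, collapse = ", "))
  score_names <- score_names %||% unique(as.character(table$score_name))
  subjects <- unique(as.character(table$subject_id))
  out <- matrix(NA_real_, nrow = length(subjects), ncol = length(score_names),
                dimnames = list(subjects, score_names))
  for (s in subjects) {
    sub <- table[table$subject_id == s, , drop = FALSE]
    for (sc in score_names) {
      rows <- sub$score_name == sc & !is.na(sub$value) & !is.na(sub$age)
      if (sum(rows) >= 2L && length(unique(sub$age[rows])) >= 2L) {
        fit <- lm(value ~ age, data = sub[rows, , drop = FALSE])
        out[s, sc] <- unname(coef(fit)[2L])
      }
    }
  }
  out
}
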