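#' Transcriptome preparation
#'
#' Regional gene-expression templates are built from point-sampled microarray
#' measurements: Gaussian kernel regression interpolates expression over
#' space, leave-one-out cross-validation selects one representative probe per
#' gene, samples are averaged within parcellation regions, and each gene is
#' z-scored across regions.
#'
#' @name transcriptome
NULL

#' Construct a regional gene-expression template
#'
#' @param matrix numeric `n_genes x n_rois` matrix, one row per gene, z-scored
#'   per gene across regions (checked unless `validate = FALSE`).
#' @param gene_ids character vector of gene identifiers (rownames used if
#'   missing).
#' @param region_ids character vector of region identifiers (colnames used if
#'   missing).
#' @param coords optional `n_rois x 3` matrix of region centroid coordinates
#'   (mm), kept for kernel-regression tests.
#' @param validate check the per-gene z-score invariant (mean 0, population SD
#'   1 within 1e-6).
#' @return an object of class `gene_template`.
#' @export
gene_template <- function(matrix, gene_ids = NULL, region_ids = NULL,
                          coords = NULL, validate = TRUE) {
  matrix <- as.matrix(matrix)
  make_ids <- function(prefix, n) if (n == 0L) character(0) else paste0(prefix, seq_len(n))
  gene_ids <- gene_ids %||% rownames(matrix) %||% make_ids("g", nrow(matrix))
  region_ids <- region_ids %||% colnames(matrix) %||% make_ids("R", ncol(matrix))
  if (length(gene_ids) != nrow(matrix) || length(region_ids) != ncol(matrix))
    stop_invalid("gene_ids/region_ids lengths must match the matrix")
  if (anyDuplicated(gene_ids)) stop_invalid("duplicate gene ids")
  if (anyDuplicated(region_ids)) stop_invalid("duplicate region ids")
  if (validate && nrow(matrix) > 0 && ncol(matrix) > 1) {
    mu <- rowMeans(matrix)
    sdp <- sqrt(rowMeans(matrix^2) - mu^2)
    if (max(abs(mu)) > 1e-6 || max(abs(sdp - 1)) > 1e-6)
      stop_invalid("template rows must be z-scored per gene across regions ",
                   "(population SD); worst |mean| = ", signif(max(abs(mu)), 3),
                   ", worst |sd-1| = ", signif(max(abs(sdp - 1)), 3))
  }
  dimnames(matrix) <- list(gene_ids, region_ids)
  structure(list(matrix = matrix, gene_ids = as.character(gene_ids),
                 region_ids = as.character(region_ids), coords = coords),
            class = "gene_template")
}

#' @export
print.gene_template <- function(x, ...) {
  cat("<gene_template> ", nrow(x$matrix), " genes x ", ncol(x$matrix),
      " regions (z-scored per gene)\n", sep = "")
  invisible(x)
}

#' Construct a set of spatial expression samples
#'
#' @param coords numeric `n_samples x 3` matrix of sample coordinates (mm).
#' @param values numeric vector of expression values, one per sample.
#' @param probe_id,gene_id identifiers (scalar or per-sample vectors).
#' @return a data.frame with columns probe_id, gene_id, x, y, z, value.
#' @export
expression_samples <- function(coords, values, probe_id = "p1", gene_id = "g1") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop_invalid("coords must have 3 columns")
  if (nrow(coords) != length(values)) stop_invalid("one value per coordinate required")
  if (!all(is.finite(coords))) stop_invalid("coordinates must be finite")
  data.frame(probe_id = probe_id, gene_id = gene_id,
             x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
             value = as.numeric(values), stringsAsFactors = FALSE)
}

#' Gaussian kernel regression of point samples
#'
#' Predicts expression at query locations as the kernel-weighted mean of the
#' sample values, with squared-exponential weights
#' `w(q, s) = exp(-||q - s||^2 / (2 sigma^2))` decreasing from proximal to
#' distal samples.  Predictions are convex combinations of the sample values.
#' Queries so distant that all weights underflow to zero fall back to the
#' nearest sample's value; the number of fallbacks is reported in the
#' `n_fallback` attribute (with a warning).
#'
#' @param samples a data.frame as returned by [expression_samples()] (columns
#'   x, y, z, value), or any data.frame with those columns.
#' @param query numeric `m x 3` matrix of query coordinates.
#' @param sigma positive kernel bandwidth (mm).  No default: the bandwidth is
#'   a modelling choice that must be stated explicitly.
#' @return numeric vector of `m` predictions, attribute `n_fallback`.
#' @export
kernel_regress <- function(samples, query, sigma) {
  sigma <- check_scalar(sigma, "sigma", lower = 0, lower_open = TRUE)
  query <- as.matrix(query)
  if (ncol(query) != 3L) stop_invalid("query must have 3 columns")
  sc <- as.matrix(samples[, c("x", "y", "z")])
  v <- samples$value
  if (nrow(sc) < 1L) stop_invalid("at least one sample required")
  # squared distances query x samples
  d2 <- outer(rowSums(query^2), rowSums(sc^2), "+") - 2 * query %*% t(sc)
  d2[d2 < 0] <- 0
  w <- exp(-d2 / (2 * sigma^2))
  tot <- rowSums(w)
  pred <- ifelse(tot > 0, (w %*% v) / tot, NA_real_)
  bad <- which(tot == 0)
  if (length(bad)) {
    nearest <- apply(d2[bad, , drop = FALSE], 1L, which.min)
    pred[bad] <- v[nearest]
    warning(length(bad), " query point(s) beyond kernel support; ",
            "nearest-sample fallback used")
  }
  pred <- as.numeric(pred)
  attr(pred, "n_fallback") <- length(bad)
  pred
}

loocv_accuracy <- function(samples, sigma) {
  n <- nrow(samples)
  if (n < 3L) return(-Inf)
  if (var(samples$value) == 0) return(-Inf)
  pred <- vapply(seq_len(n), function(i) {
    suppressWarnings(
      kernel_regress(samples[-i, , drop = FALSE],
                     as.matrix(samples[i, c("x", "y", "z")]), sigma))
  }, numeric(1))
  if (sd(pred) == 0) return(-Inf)
  cor(samples$value, pred)
}

#' Select the representative probe of a gene by LOOCV accuracy
#'
#' For each candidate probe, every sample is predicted from the remaining
#' samples of that probe via [kernel_regress()]; the probe's accuracy is the
#' Pearson correlation between observed and leave-one-out predicted values.
#' The probe with the highest accuracy is selected.  Probes with fewer than 3
#' samples or zero variance are assigned accuracy `-Inf`; exact ties are
#' broken by lowest probe index (input order).
#'
#' @param probes list of sample data.frames (one per probe, same gene), or a
#'   single data.frame with a `probe_id` column to split on.
#' @param sigma positive kernel bandwidth passed to [kernel_regress()].
#' @return list with elements `probe_id` (selected), `index`, and `accuracy`
#'   (named numeric vector over probes, in input order).
#' @export
select_probe_loocv <- function(probes, sigma) {
  if (is.data.frame(probes))
    probes <- split(probes, factor(probes$probe_id, levels = unique(probes$probe_id)))
  if (length(probes) < 1L) stop_invalid("at least one probe required")
  acc <- vapply(probes, loocv_accuracy, numeric(1), sigma = sigma)
  ids <- vapply(seq_along(probes), function(i)
    as.character(probes[[i]]$probe_id[1L] %||% i), character(1))
  names(acc) <- ids
  if (all(!is.finite(acc)))
    stop(errorCondition("no valid probe: all probes degenerate (fewer than 3 samples or zero variance)",
                        class = c("gemcm_no_valid_probe", "error")))
  best <- which.max(acc)   # which.max returns the first maximum: lowest index
  list(probe_id = ids[best], index = unname(best), accuracy = acc)
}

#' Build a regional gene-expression template from assigned samples
#'
#' Averages each gene's sample values within regions, fills regions with no
#' samples by kernel regression at the region centroid, and z-scores each
#' gene across regions (population SD).  Genes constant across all regions
#' cannot be z-scored; they are dropped and reported in the `degenerate`
#' attribute.
#'
#' @param samples data.frame with columns gene_id, x, y, z, value (one
#'   representative probe per gene, e.g. after [select_probe_loocv()]).
#' @param region_assignment integer or character vector mapping each sample
#'   row to a region; `NA` marks samples outside the parcellation.
#' @param region_ids character vector of all region identifiers (defines
#'   template columns and order).
#' @param region_centroids optional `n_rois x 3` matrix of centroids, required
#'   only when some region receives no sample.
#' @param sigma kernel bandwidth for centroid fill-in.
#' @return a [gene_template()]; attribute `degenerate` lists excluded genes.
#' @export
build_template <- function(samples, region_assignment, region_ids,
                           region_centroids = NULL, sigma = NULL) {
  region_ids <- as.character(region_ids)
  if (length(region_assignment) != nrow(samples))
    stop_invalid("one region assignment per sample required")
  reg <- as.character(region_assignment)
  if (!all(stats::na.omit(reg) %in% region_ids))
    stop_invalid("region_assignment contains unknown region ids")
  genes <- unique(samples$gene_id)
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(region_ids),
                dimnames = list(genes, region_ids))
  for (g in genes) {
    rows <- samples$gene_id == g
    sub <- samples[rows, , drop = FALSE]
    means <- tapply(sub$value, factor(reg[rows], levels = region_ids), mean)
    empty <- is.na(means)
    if (any(empty)) {
      if (is.null(region_centroids) || is.null(sigma))
        stop_invalid("regions without samples (",
                     paste(region_ids[empty], collapse = ", "),
                     ") require region_centroids and sigma for fill-in")
      means[empty] <- kernel_regress(
        sub, as.matrix(region_centroids)[empty, , drop = FALSE], sigma)
    }
    mat[g, ] <- means
  }
  mu <- rowMeans(mat)
  sdp <- sqrt(pmax(rowMeans(mat^2) - mu^2, 0))
  degenerate <- rownames(mat)[sdp == 0]
  if (length(degenerate)) {
    warning("excluding ", length(degenerate),
            " gene(s) constant across regions: ",
            paste(degenerate, collapse = ", "))
    keep <- sdp > 0
    mat <- mat[keep, , drop = FALSE]
    mu <- mu[keep]; sdp <- sdp[keep]
  }
  z <- (mat - mu) / sdp
  out <- gene_template(z)
  attr(out, "degenerate") <- degenerate
  out
}

#' Z-score a genes-by-regions matrix per gene
#'
#' Population-SD convention (divisor `n`), matching the template invariant.
#'
#' @param mat numeric matrix, genes in rows.
#' @return matrix of the same shape with row means 0 and population SD 1.
#' @export
zscore_rows <- function(mat) {
  mu <- rowMeans(mat)
  sdp <- sqrt(rowMeans(mat^2) - mu^2)
  if (any(sdp == 0)) stop_invalid("cannot z-score constant rows")
  (mat - mu) / sdp
}
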