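#' File I/O contracts
#'
#' All tabular interchange uses TSV with full-precision scientific formatting
#' (lossless round trip to better than 1e-15 relative), a header row of
#' column labels and a first column of row labels.  Cohorts are serialized to
#' a directory of TSV files plus a JSON manifest recording the configuration
#' and seed.
#'
#' @name cli_io
NULL

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write a labelled numeric matrix as TSV
#'
#' @param mat numeric matrix with (or without) dimnames.
#' @param path output file path.
#' @param row_label header of the row-name column (default "id").
#' @export
write_matrix <- function(mat, path, row_label = "id") {
  mat <- as.matrix(mat)
  rn <- rownames(mat) %||% paste0("r", seq_len(nrow(mat)))
  cn <- colnames(mat) %||% paste0("c", seq_len(ncol(mat)))
  body <- matrix(fmt_num(mat), nrow = nrow(mat))
  lines <- c(paste(c(row_label, cn), collapse = "\t"),
             vapply(seq_len(nrow(mat)), function(i)
               paste(c(rn[i], body[i, ]), collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a labelled numeric matrix from TSV
#'
#' Strict parse: every row must have the same number of fields as the header
#' (ragged rows are reported with their line number) and labels must be
#' unique.
#'
#' @param path TSV file written by [write_matrix()] (or equivalent).
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop_invalid("empty file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1L]])
  widths <- vapply(fields, length, integer(1))
  if (any(widths != width))
    stop_invalid("ragged TSV ", path, ": line(s) ",
                 paste(which(widths != width), collapse = ", "),
                 " have a field count differing from the header")
  header <- fields[[1L]][-1L]
  rows <- fields[-1L]
  rn <- vapply(rows, `[`, character(1), 1L)
  if (anyDuplicated(rn)) stop_invalid("duplicate row label(s) in ", path, ": ",
                                      paste(unique(rn[duplicated(rn)]), collapse = ", "))
  if (anyDuplicated(header)) stop_invalid("duplicate column label(s) in ", path)
  mat <- matrix(NA_real_, length(rows), width - 1L, dimnames = list(rn, header))
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]][-1L]))
    if (anyNA(v) && any(rows[[i]][-1L][is.na(v)] != "NA"))
      stop_invalid("non-numeric value in ", path, " at line ", i + 1L)
    mat[i, ] <- v
  }
  mat
}

write_manifest <- function(path, ...) {
  info <- list(..., r_version = as.character(getRversion()),
               package_version = as.character(utils::packageVersion("gemcm")),
               written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(info, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Serialize a synthetic cohort to a directory
#'
#' Writes `template.tsv` (genes x regions), `connectome.tsv`,
#' `cognition.tsv` (long format), one `trajectory_<subject>.tsv` per subject
#' (long format: factor, region, time, value), `true_params.tsv` (stacked
#' gene-modulation parameters), `true_latent.tsv`, and `manifest.json` with
#' the full configuration and seed.
#'
#' @param cohort a [gen_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(cohort$template$matrix, file.path(dir, "template.tsv"), "gene")
  write_matrix(cohort$connectome, file.path(dir, "connectome.tsv"), "region")
  cog <- cohort$cognitive
  writeLines(c("subject_id\tage\tscore_name\tvalue",
               paste(cog$subject_id, fmt_num(cog$age), cog$score_name,
                     fmt_num(cog$value), sep = "\t")),
             file.path(dir, "cognition.tsv"))
  for (s in names(cohort$subjects)) {
    ts <- cohort$subjects[[s]]
    d <- dim(ts$values)
    long <- data.frame(
      factor = rep(ts$factor_names, times = d[2L] * d[3L]),
      region = rep(rep(ts$region_ids, each = d[1L]), times = d[3L]),
      time = rep(ts$times, each = d[1L] * d[2L]),
      value = as.vector(ts$values))
    writeLines(c("factor\tregion\ttime\tvalue",
                 paste(long$factor, long$region, fmt_num(long$time),
                       fmt_num(long$value), sep = "\t")),
               file.path(dir, paste0("trajectory_", s, ".tsv")))
  }
  write_matrix(stack_gene_params(cohort$true_params,
                                 cohort$template$gene_ids,
                                 cohort$subjects[[1L]]$factor_names),
               file.path(dir, "true_params.tsv"), "subject")
  write_matrix(matrix(cohort$true_latent, ncol = 1,
                      dimnames = list(names(cohort$true_latent), "loading")),
               file.path(dir, "true_latent.tsv"), "parameter")
  write_manifest(file.path(dir, "manifest.json"),
                 kind = "synthetic_cohort",
                 config = unclass(cohort$config),
                 subjects = names(cohort$subjects))
  invisible(dir)
}

#' Read a serialized cohort directory
#'
#' Inverse of [write_cohort()] for the inputs the fitting stage needs
#' (template, connectome, trajectories, cognition); true parameters and the
#' latent direction are reloaded when present.
#'
#' @param dir directory written by [write_cohort()].
#' @return a list with elements `template`, `connectome`, `subjects`,
#'   `cognitive`, and (when present) `true_params_matrix`, `true_latent`,
#'   `config`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  tmat <- read_matrix(file.path(dir, "template.tsv"))
  template <- gene_template(tmat)
  conn <- read_matrix(file.path(dir, "connectome.tsv"))
  cog <- read.delim(file.path(dir, "cognition.tsv"), sep = "\t",
                    stringsAsFactors = FALSE)
  subj_ids <- manifest$subjects
  subjects <- lapply(subj_ids, function(s) {
    long <- read.delim(file.path(dir, paste0("trajectory_", s, ".tsv")),
                       sep = "\t", stringsAsFactors = FALSE)
    factors <- unique(long$factor); regions <- unique(long$region)
    times <- sort(unique(long$time))
    arr <- array(long$value,
                 dim = c(length(factors), length(regions), length(times)))
    subject_timeseries(arr, times, factors, regions)
  })
  names(subjects) <- subj_ids
  out <- list(template = template, connectome = conn, subjects = subjects,
              cognitive = cog, config = manifest$config)
  tp <- file.path(dir, "true_params.tsv")
  if (file.exists(tp)) out$true_params_matrix <- read_matrix(tp)
  tl <- file.path(dir, "true_latent.tsv")
  if (file.exists(tl)) {
    m <- read_matrix(tl)
    out$true_latent <- setNames(m[, 1L], rownames(m))
  }
  out
}
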