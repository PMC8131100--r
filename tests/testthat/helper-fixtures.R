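# Small deterministic fixtures shared across test files.

# A hand-buildable model problem: trajectories simulated by the package's
# forward dynamics from known sparse parameters.
make_toy_problem <- function(n_factors = 3, n_rois = 8, n_genes = 6,
                             n_times = 4, seed = 42, effect = 0.05,
                             beta = 0.01) {
  set.seed(seed)
  template <- gen_gene_expression(n_genes, n_rois, lengthscale = 20, seed = seed)
  conn <- gen_connectome(n_rois, density = 0.5, seed = seed + 1)
  params <- lapply(seq_len(n_factors), function(m) {
    ag <- matrix(0, n_genes, n_factors)
    ag[sample.int(n_genes * n_factors, 4)] <- effect * sample(c(-1, 1), 4, TRUE)
    factor_params(rnorm(n_factors, 0, 0.02), ag, beta, paste0("F", m))
  })
  s0 <- matrix(runif(n_factors * n_rois, 0.5, 1.5), n_factors, n_rois)
  times <- seq(0, by = 1, length.out = n_times)
  ts <- simulate_forward(params, s0, times, template, conn,
                         region_ids = template$region_ids)
  list(template = template, conn = conn, params = params, s0 = s0,
       times = times, ts = ts)
}

# Probe sample sets on a 1-d line embedded in 3-d, for kernel-regression and
# probe-selection tests.
make_line_samples <- function(n = 20, spacing = 1, value_fun = function(x) x,
                              probe_id = "p1", gene_id = "g1") {
  x <- seq(0, by = spacing, length.out = n)
  expression_samples(cbind(x, 0, 0), value_fun(x), probe_id, gene_id)
}

# Monte-Carlo SE of a chain mean by batch means (accounts for autocorrelation)
mcse_batch <- function(samples, n_batch = 50) {
  apply(samples, 2, function(s) {
    b <- colMeans(matrix(s, nrow = length(s) %/% n_batch))
    sd(b) / sqrt(n_batch)
  })
}

expect_within <- function(x, lo, hi, label = deparse(substitute(x))) {
  expect_true(x >= lo && x <= hi,
              label = sprintf("%s = %g not in [%g, %g]", label, x, lo, hi))
}
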