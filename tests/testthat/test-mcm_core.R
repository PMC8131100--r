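test_that("finite differences concatenate time-major with the documented length", {
  # 138 regions, 4 visits -> 138 * 3 = 414 derivative values
  set.seed(1)
  arr <- array(rnorm(1 * 138 * 4), dim = c(1, 138, 4))
  ts <- subject_timeseries(arr, 0:3)
  d <- finite_difference_derivatives(ts, 1)
  expect_length(as.numeric(d), 414)
  expect_identical(attr(d, "left_index"), rep(1:3, each = 138))

  # constant trajectory -> all zero
  ts0 <- subject_timeseries(array(2, dim = c(2, 5, 3)), c(0, 1, 3))
  expect_equal(as.numeric(finite_difference_derivatives(ts0, 2)), rep(0, 10))

  # exact line S = a + b t -> every entry equals b, for irregular spacing
  b <- seq(-1, 1, length.out = 5)
  tms <- c(0, 0.5, 2, 3.5)
  arr <- array(NA_real_, dim = c(1, 5, 4))
  for (k in seq_along(tms)) arr[1, , k] <- 3 + b * tms[k]
  d <- finite_difference_derivatives(subject_timeseries(arr, tms), 1)
  expect_equal(as.numeric(d), rep(b, 3), tolerance = 1e-12)
})

test_that("non-increasing times are rejected", {
  expect_error(subject_timeseries(array(0, c(1, 2, 3)), c(0, 1, 1)),
               class = "gemcm_invalid_argument")
})

test_that("design matrix has the documented column counts", {
  tmpl976 <- gene_template(matrix(rnorm(976 * 4), 976, 4) |> zscore_rows())
  conn <- gen_connectome(4, 1, seed = 2)
  ts <- subject_timeseries(array(runif(6 * 4 * 2, 0.5, 1.5), c(6, 4, 2)), 0:1,
                           region_ids = tmpl976$region_ids)
  X <- build_design_matrix(ts, tmpl976, conn, 1)
  expect_identical(dim(X), c(4L, 5863L))
  expect_identical(sum(grepl("^alpha0:", colnames(X))), 6L)
  expect_identical(sum(grepl("^g[0-9]+:", colnames(X))), 5856L)

  # empty gene block: 6 + 0 + 1 columns
  tmpl0 <- gene_template(matrix(numeric(0), 0, 4,
                                dimnames = list(NULL, tmpl976$region_ids)))
  expect_identical(ncol(build_design_matrix(ts, tmpl0, conn, 1)), 7L)
})

test_that("design matrix entries equal explicit elementwise evaluation", {
  # n_genes=2, n_factors=2, n_rois=3: hand-loop every term of the model
  G <- zscore_rows(matrix(c(1, 2, 4, 0, 3, 1), 2, 3, byrow = TRUE))
  tmpl <- gene_template(G)
  C <- matrix(c(0, 2, 1, 2, 0, 3, 1, 3, 0), 3, 3)
  dimnames(C) <- list(tmpl$region_ids, tmpl$region_ids)
  S <- array(c(0.9, 1.1, 1.2, 0.8, 1.0, 1.3,
               1.0, 1.2, 1.1, 0.7, 1.1, 1.2), dim = c(2, 3, 2))
  ts <- subject_timeseries(S, c(0, 1), region_ids = tmpl$region_ids)
  for (m in 1:2) {
    X <- build_design_matrix(ts, tmpl, C, m)
    expect_identical(dim(X), c(3L, 2L + 4L + 1L))
    for (i in 1:3) {
      for (n in 1:2) expect_equal(unname(X[i, n]), S[n, i, 1])
      col <- 2L
      for (k in 1:2) for (n in 1:2) {
        col <- col + 1L
        expect_equal(unname(X[i, col]), G[k, i] * S[n, i, 1])
      }
      spread <- 0
      for (j in 1:3) if (j != i) spread <- spread + C[j, i] * (S[m, j, 1] - S[m, i, 1])
      expect_equal(unname(X[i, 7L]), spread)
    }
  }
})

test_that("region-id mismatches raise an alignment error naming offenders", {
  toy <- make_toy_problem()
  bad <- toy$template
  bad$region_ids[1] <- "nope"
  colnames(bad$matrix)[1] <- "nope"
  expect_error(build_design_matrix(toy$ts, bad, toy$conn, 1), "R1")
})

test_that("zero parameters freeze the trajectory; symmetric spreading conserves mass", {
  n_f <- 2; n_r <- 6
  tmpl <- gen_gene_expression(3, n_r, 10, seed = 5)
  conn <- gen_connectome(n_r, 0.8, seed = 6)
  zero <- lapply(1:n_f, function(m)
    factor_params(rep(0, n_f), matrix(0, 3, n_f), 0, m))
  s0 <- matrix(runif(n_f * n_r, 0.5, 1.5), n_f, n_r)
  ts <- simulate_forward(zero, s0, 0:4, tmpl, conn)
  for (k in 2:5) expect_equal(ts$values[, , k], s0)

  # pure spreading with symmetric C: per-factor totals are conserved exactly
  # under Euler because the exchange term is antisymmetric in (i, j)
  spread_only <- lapply(1:n_f, function(m)
    factor_params(rep(0, n_f), matrix(0, 3, n_f), 0.05, m))
  ts2 <- simulate_forward(spread_only, s0, 0:4, tmpl, conn)
  tot0 <- rowSums(s0)
  for (k in 2:5) expect_equal(rowSums(ts2$values[, , k]), tot0, tolerance = 1e-12)
})

test_that("forward simulation and design matrix satisfy the exact linear identity", {
  toy <- make_toy_problem(n_factors = 3, n_rois = 10, n_genes = 8, n_times = 5)
  for (m in 1:3) {
    y <- as.numeric(finite_difference_derivatives(toy$ts, m))
    X <- build_design_matrix(toy$ts, toy$template, toy$conn, m)
    th <- flatten_params(toy$params[[m]])
    expect_lt(max(abs(y - as.numeric(X %*% th))), 1e-10)
  }
})

test_that("derivatives are scale-equivariant in the parameters at the first step", {
  toy <- make_toy_problem(n_times = 2)
  scaled <- lapply(toy$params, function(p)
    factor_params(3 * p$alpha0, 3 * p$alpha_gene, 3 * p$beta_spread, p$target_factor))
  ts1 <- simulate_forward(toy$params, toy$s0, c(0, 1), toy$template, toy$conn)
  ts3 <- simulate_forward(scaled, toy$s0, c(0, 1), toy$template, toy$conn)
  d1 <- as.numeric(finite_difference_derivatives(ts1, 1))
  d3 <- as.numeric(finite_difference_derivatives(ts3, 1))
  expect_equal(d3, 3 * d1, tolerance = 1e-12)
})

test_that("unstable dynamics raise a simulation-unstable error with the step", {
  tmpl <- gen_gene_expression(2, 4, 10, seed = 1)
  conn <- gen_connectome(4, 1, seed = 1)
  boom <- lapply(1:2, function(m)
    factor_params(rep(5, 2), matrix(0, 2, 2), 0, m))
  expect_error(
    simulate_forward(boom, matrix(1, 2, 4), 0:20, tmpl, conn,
                     magnitude_bound = 100),
    class = "gemcm_simulation_unstable")
})

test_that("column ordering is stable (fingerprint on a fixed seed)", {
  toy <- make_toy_problem(seed = 7)
  X <- build_design_matrix(toy$ts, toy$template, toy$conn, 2)
  expect_identical(colnames(X)[1:4], c("alpha0:F1->F2", "alpha0:F2->F2",
                                       "alpha0:F3->F2", "g1:F1->F2"))
  expect_identical(colnames(X)[ncol(X)], "spread->F2")
  # numeric fingerprint: checksum frozen from the documented layout
  expect_equal(sum(X[1, ] * seq_len(ncol(X))), 42.575102668, tolerance = 1e-6)
})

test_that("r2_score matches its definition and SNR calibration", {
  obs <- c(1, 2, 3, 5)
  expect_equal(r2_score(obs, obs), 1)
  expect_equal(r2_score(obs, rep(mean(obs), 4)), 0)
  expect_warning(r2 <- r2_score(rep(1, 4), c(1, 1, 1, 2)), "zero variance")
  expect_true(is.na(r2))

  # observed = signal + noise at known SNR -> R2 ~= SNR / (SNR + 1)
  set.seed(11)
  snr <- 4
  r2s <- replicate(40, {
    sig <- rnorm(300)
    obs <- sig + rnorm(300, 0, sqrt(1 / snr))
    r2_score(obs, sig)
  })
  expect_within(mean(r2s), snr / (snr + 1) - 0.02, snr / (snr + 1) + 0.02)
})

test_that("parameter flattening round-trips and matches the documented length", {
  p <- factor_params(1:3 / 10, matrix(rnorm(12), 4, 3), -0.2, "F1")
  th <- flatten_params(p)
  expect_length(th, 3 + 12 + 1)
  q <- unflatten_params(th, 4, 3, "F1")
  expect_equal(q$alpha0, p$alpha0)
  expect_equal(q$alpha_gene, p$alpha_gene)
  expect_equal(q$beta_spread, p$beta_spread)
})
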