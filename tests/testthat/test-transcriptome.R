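test_that("kernel regression reproduces constant fields and respects convexity", {
  set.seed(3)
  samp <- expression_samples(matrix(runif(30), 10, 3), rep(4.2, 10))
  q <- matrix(runif(15), 5, 3)
  expect_equal(kernel_regress(samp, q, sigma = 0.3), rep(4.2, 5),
               ignore_attr = TRUE)

  # convex-combination invariant over random fields and bandwidths
  for (i in 1:5) {
    samp <- expression_samples(matrix(runif(60, 0, 10), 20, 3), rnorm(20))
    pred <- kernel_regress(samp, matrix(runif(30, 0, 10), 10, 3),
                           sigma = runif(1, 0.5, 5))
    expect_true(all(pred >= min(samp$value) - 1e-12))
    expect_true(all(pred <= max(samp$value) + 1e-12))
  }
})

test_that("kernel regression approaches the delta limit at a sample point", {
  samp <- make_line_samples(10, spacing = 1, value_fun = function(x) x^2)
  at <- as.matrix(samp[4, c("x", "y", "z")])
  expect_equal(as.numeric(kernel_regress(samp, at, sigma = 1e-3)),
               samp$value[4], tolerance = 1e-9)
})

test_that("kernel regression recovers a linear field at interior queries", {
  samp <- make_line_samples(20, spacing = 1)        # values = x coordinate
  qx <- seq(5.5, 13.5, by = 1)
  pred <- kernel_regress(samp, cbind(qx, 0, 0), sigma = 1)
  # oracle: evaluate the weighted-mean formula directly with explicit loops
  oracle <- vapply(qx, function(q) {
    w <- exp(-(q - samp$x)^2 / 2)
    sum(w * samp$value) / sum(w)
  }, numeric(1))
  expect_equal(as.numeric(pred), oracle, tolerance = 1e-12)
  expect_true(all(abs(pred - qx) / qx < 0.05))
})

test_that("distant queries fall back to the nearest sample with a warning", {
  samp <- make_line_samples(5)
  expect_warning(
    pred <- kernel_regress(samp, cbind(1e6, 0, 0), sigma = 0.5),
    "fallback")
  expect_equal(as.numeric(pred), samp$value[5])
  expect_identical(attr(pred, "n_fallback"), 1L)
})

test_that("LOOCV probe selection prefers the spatially smooth probe", {
  set.seed(9)
  smooth <- make_line_samples(30, value_fun = function(x) sin(x / 5),
                              probe_id = "smooth")
  noisy <- smooth
  noisy$probe_id <- "noisy"
  noisy$value <- sample(noisy$value)          # same marginal, no spatial structure
  sel <- select_probe_loocv(list(noisy, smooth), sigma = 1.5)
  expect_identical(sel$probe_id, "smooth")
  expect_gt(sel$accuracy["smooth"], sel$accuracy["noisy"])

  # single probe returned unconditionally
  expect_identical(select_probe_loocv(list(smooth), sigma = 1)$probe_id, "smooth")

  # degenerate probes: < 3 samples or zero variance -> -Inf; all degenerate errors
  tiny <- make_line_samples(2, probe_id = "tiny")
  flat <- make_line_samples(10, value_fun = function(x) rep(1, length(x)),
                            probe_id = "flat")
  sel2 <- select_probe_loocv(list(tiny, smooth, flat), sigma = 1.5)
  expect_identical(sel2$probe_id, "smooth")
  expect_identical(unname(sel2$accuracy[c("tiny", "flat")]), c(-Inf, -Inf))
  expect_error(select_probe_loocv(list(tiny, flat), sigma = 1),
               class = "gemcm_no_valid_probe")
})

test_that("probe selection is permutation-invariant up to the declared tie-break", {
  set.seed(21)
  a <- make_line_samples(25, value_fun = function(x) cos(x / 4), probe_id = "a")
  b <- make_line_samples(25, value_fun = function(x) cos(x / 4) + rnorm(25, 0, 0.4),
                         probe_id = "b")
  expect_identical(select_probe_loocv(list(a, b), 2)$probe_id,
                   select_probe_loocv(list(b, a), 2)$probe_id)
  # exact tie (identical probes under different ids) -> lowest index wins
  a2 <- a; a2$probe_id <- "zz_copy"
  expect_identical(select_probe_loocv(list(a, a2), 2)$probe_id, "a")
  expect_identical(select_probe_loocv(list(a2, a), 2)$probe_id, "zz_copy")
})

test_that("template building averages within regions and z-scores per gene", {
  # one gene, regional values 1..5 -> z-scores of 1..5 (population SD), monotone
  samp <- expression_samples(matrix(runif(15), 5, 3), 1:5, gene_id = "gA")
  tmpl <- build_template(samp, paste0("R", 1:5), paste0("R", 1:5))
  z <- tmpl$matrix["gA", ]
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_true(all(diff(z) > 0))
  expect_equal(unname(z), unname((1:5 - 3) / sqrt(2)), tolerance = 1e-12)

  # two samples in one region average before z-scoring
  samp2 <- expression_samples(matrix(runif(9), 3, 3), c(2, 4, 10), gene_id = "gB")
  tmpl2 <- build_template(samp2, c("R1", "R1", "R2"), c("R1", "R2"))
  raw <- tmpl2$matrix["gB", ] # z of (3, 10): mean 6.5, sd 3.5
  expect_equal(unname(raw), c(-1, 1), tolerance = 1e-12)

  # constant gene excluded with a warning
  both <- rbind(samp, expression_samples(matrix(runif(15), 5, 3),
                                         rep(7, 5), gene_id = "gC"))
  expect_warning(tmpl3 <- build_template(both, rep(paste0("R", 1:5), 2),
                                         paste0("R", 1:5)),
                 "constant")
  expect_identical(tmpl3$gene_ids, "gA")
  expect_identical(attr(tmpl3, "degenerate"), "gC")
})

test_that("regions without samples are filled by kernel regression at centroids", {
  samp <- make_line_samples(6, gene_id = "gA")
  centroids <- cbind(c(0.5, 2.5, 4.5), 0, 0)
  # assign samples only to R1 and R2; R3 has no samples
  tmpl <- build_template(samp, c("R1", "R1", "R2", "R2", "R1", "R2"),
                         paste0("R", 1:3), centroids, sigma = 1)
  expect_identical(dim(tmpl$matrix), c(1L, 3L))
  expect_error(build_template(samp, c("R1", "R1", "R2", "R2", "R1", "R2"),
                              paste0("R", 1:3)),
               "region_centroids")
})
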