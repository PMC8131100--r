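test_that("stability filter keeps constant-signal and drops exact-null parameters", {
  set.seed(17)
  P <- cbind(ones = rep(1, 20),
             null = c(rep(1, 10), rep(-1, 10)),      # mean exactly 0
             noise = rnorm(20))
  kept <- stability_filter(P, 0.99)
  expect_true("ones" %in% names(kept))
  expect_false("null" %in% names(kept))
})

test_that("stability filter retains about 1% of pure-noise parameters at 99% CI", {
  set.seed(18)
  P <- matrix(rnorm(100 * 5000), 100, 5000)
  frac <- length(stability_filter(P, 0.99)) / 5000
  band <- 3 * sqrt(0.01 * 0.99 / 5000)
  expect_within(frac, 0.01 - band, 0.01 + band)
})

test_that("cross-block SVD finds a planted driver and normalizes variance", {
  set.seed(19)
  n <- 200
  driver <- rnorm(n)
  P <- cbind(drv = driver, n1 = rnorm(n), n2 = rnorm(n))
  S <- cbind(sc = driver)
  res <- svd_pls(P, S)
  expect_gt(res$explained_variance[1], 0.95)
  expect_identical(rownames(res$saliences)[which.max(abs(res$saliences[, 1]))],
                   "drv")
  expect_equal(sum(res$explained_variance), 1, tolerance = 1e-12)

  # independent blocks: EV sums to 1 over min(p, q) components, first < 1
  P2 <- matrix(rnorm(n * 7), n, 7); S2 <- matrix(rnorm(n * 5), n, 5)
  r2 <- svd_pls(P2, S2)
  expect_length(r2$singular_values, 5)
  expect_lt(r2$explained_variance[1], 1)
  expect_equal(sum(r2$explained_variance), 1, tolerance = 1e-12)
})

test_that("component signs follow the largest-loading convention", {
  set.seed(20)
  driver <- rnorm(100)
  P <- cbind(rnorm(100), drv = driver)
  S <- cbind(a = -driver + rnorm(100, 0, 0.1), b = 0.2 * driver + rnorm(100))
  res <- svd_pls(P, S)
  j <- which.max(abs(res$score_loadings[, 1]))
  expect_gt(res$score_loadings[j, 1], 0)
})

test_that("permutation p-values respect the add-one rule and detect perfect association", {
  set.seed(21)
  x <- rnorm(40)
  P <- cbind(x, rnorm(40), rnorm(40))
  S <- cbind(x)                      # perfect association
  p <- permutation_component_test(P, S, n_perm = 999, seed = 2)
  expect_equal(p[1], 1 / 1000, tolerance = 1e-12)
  expect_true(all(p >= 1 / 1000 & p <= 1))
  expect_error(permutation_component_test(P, S, n_perm = 0),
               class = "gemcm_invalid_argument")
})

test_that("permutation test attains nominal type-I error under the null", {
  set.seed(22)
  n_rep <- 200
  rej <- vapply(seq_len(n_rep), function(r) {
    P <- matrix(rnorm(30 * 8), 30, 8)
    S <- matrix(rnorm(30 * 3), 30, 3)
    permutation_component_test(P, S, n_perm = 99, seed = r)[1] <= 0.05
  }, logical(1))
  band <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_within(mean(rej), 0.05 - band, 0.05 + band)
})

test_that("bootstrap ratios single out a planted driver and respect the threshold", {
  set.seed(23)
  n <- 200
  driver <- rnorm(n)
  # per-column false-selection probability is ~1% (selection needs the sample
  # correlation to exceed ~2.58/sqrt(n)); a wide noise panel keeps the
  # empirical fraction well-resolved
  P <- cbind(drv = driver + rnorm(n, 0, 0.2),
             matrix(rnorm(n * 200), n, 200,
                    dimnames = list(NULL, paste0("ns", 1:200))))
  S <- cbind(sc = driver + rnorm(n, 0, 0.2))
  br <- bootstrap_ratios(P, S, component = 1, n_boot = 2000, seed = 3)
  expect_gt(abs(br$ratios["drv"]), 2.58)
  expect_true("drv" %in% br$selected)
  noise_sel <- mean(paste0("ns", 1:200) %in% br$selected)
  expect_lt(noise_sel, 0.05)

  # threshold = Inf -> empty selection
  br_inf <- bootstrap_ratios(P, S, n_boot = 200, seed = 4, threshold = Inf)
  expect_length(br_inf$selected, 0)

  # sign alignment alternative gives the same driver
  br_sign <- bootstrap_ratios(P, S, n_boot = 500, seed = 5, align = "sign")
  expect_true("drv" %in% br_sign$selected)
})

test_that("gene ranking parses labels, sorts by |salience| and breaks ties by label", {
  sal <- c("gA:F1->F2" = 0.5, "gB:F2->F1" = -0.8, "gC:F1->F1" = 0.5)
  rat <- c("gA:F1->F2" = 3, "gB:F2->F1" = -4, "gC:F1->F1" = 3.2)
  tab <- rank_genes(names(sal), sal, rat)
  expect_identical(tab$gene, c("gB", "gA", "gC"))
  expect_identical(tab$source_factor[1], "F2")
  expect_identical(tab$target_factor[1], "F1")

  single <- rank_genes("gA:F1->F2", sal, rat)
  expect_identical(nrow(single), 1L)
  empty <- rank_genes(character(0), numeric(0), numeric(0))
  expect_identical(nrow(empty), 0L)
})

test_that("the population pipeline recovers the latent-loaded parameter subset", {
  co <- gen_cohort(cohort_config(n_subjects = 30, n_rois = 10, n_genes = 12,
                                 n_active_params = 6, seed = 24))
  tru <- stack_gene_params(co$true_params, co$template$gene_ids)
  slopes <- cognitive_slopes(co$cognitive)[rownames(tru), ]
  res <- analyze_parameters(tru, slopes, n_perm = 500, n_boot = 500, seed = 4)
  loaded <- names(co$true_latent)[co$true_latent != 0]
  expect_lt(res$component_pvalues[1], 0.05)
  expect_gte(mean(loaded %in% res$bootstrap$selected), 0.8)
  false_frac <- mean(!(res$bootstrap$selected %in% loaded))
  expect_lt(false_frac, 0.2)
  expect_true(all(res$gene_table$gene %in% co$template$gene_ids))
})
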