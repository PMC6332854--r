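test_that("single-SNP variance formula matches the published arithmetic", {
  expect_equal(round(snp_variance(0.094, 0.40), 3), 0.027)
  expect_equal(round(snp_variance(0.185, 0.30), 3), 0.027)
  expect_equal(snp_variance(0.3, 0), 0)
  # symmetric in p <-> 1-p and in the sign of a
  expect_equal(snp_variance(0.2, 0.4), snp_variance(0.8, 0.4))
  expect_equal(snp_variance(0.2, 0.4), snp_variance(0.2, -0.4))
  expect_error(snp_variance(0, 0.4), "frequency")
  expect_error(snp_variance(1.2, 0.4), "frequency")
})

test_that("haplotype variance equals the brute-force pairwise sum", {
  expect_equal(haplotype_variance(1, 5), 0)
  expect_equal(haplotype_variance(c(0.5, 0.5), c(1, 0)), 0.25)
  set.seed(61)
  for (i in 1:300) {
    k <- sample(2:8, 1)
    p <- rand_freqs(k)
    a <- rnorm(k)
    v <- haplotype_variance(p, a)
    expect_equal(v, brute_hap_variance(p, a), tolerance = 1e-10)
    # equals the frequency-weighted variance of the effects
    expect_equal(v, sum(p * (a - sum(p * a))^2), tolerance = 1e-10)
    # permutation invariance
    o <- sample(k)
    expect_equal(haplotype_variance(p[o], a[o]), v, tolerance = 1e-12)
  }
  expect_error(haplotype_variance(c(0.5, 0.4), c(1, 0)), "sum")
})

test_that("the k = 2 pairwise form is half the SNP formula, by convention", {
  set.seed(62)
  for (i in 1:20) {
    p <- runif(1, 0.05, 0.95)
    a <- rnorm(2)
    expect_equal(haplotype_variance(c(p, 1 - p), a),
                 0.5 * snp_variance(p, a[1] - a[2]), tolerance = 1e-12)
    expect_equal(haplotype_variance(c(p, 1 - p), a, scale = "snp_consistent"),
                 snp_variance(p, a[1] - a[2]), tolerance = 1e-12)
  }
})

test_that("moment gamma fit recovers parameters and matches an ML oracle", {
  set.seed(63)
  x <- rgamma(10000, shape = 2, rate = 3)
  f <- fit_gamma_mom(x)
  expect_equal(f$alpha, 2, tolerance = 0.05)
  expect_equal(f$beta, 3, tolerance = 0.05)
  ml <- fitdistrplus::fitdist(x, "gamma", method = "mle")
  expect_lt(abs(f$alpha - ml$estimate[["shape"]]) / ml$estimate[["shape"]], 0.02)
  expect_lt(abs(f$beta - ml$estimate[["rate"]]) / ml$estimate[["rate"]], 0.02)

  expect_error(fit_gamma_mom(c(1, 0, 2)), "positive")
  expect_error(fit_gamma_mom(rep(2, 10)), "constant")
  expect_error(fit_gamma_mom(1.5), "at least 2")
})

test_that("parameter smoothing recovers known generating curves", {
  k <- 2:12
  alpha <- 0.8 + 0.05 * k - 0.002 * k^2 + 5e-5 * k^3
  set.seed(64)
  beta <- 5 * (1 - 0.8 * exp(-0.3 * k)) + rnorm(length(k), 0, 0.01)
  classes <- data.frame(k = k, n = rep(50L, length(k)), s = NA, alpha = alpha,
                        beta = beta, mu = alpha / beta)
  sm <- smooth_params(classes)
  expect_equal(sm$cubic_coef, c(0.8, 0.05, -0.002, 5e-5), tolerance = 1e-6)
  expect_equal(sm$brody$A, 5, tolerance = 0.05)
  expect_equal(sm$brody$B, 0.8, tolerance = 0.05)
  expect_equal(sm$brody$kappa, 0.3, tolerance = 0.05)
  # asymptote property: beta(k) -> A for large k
  expect_equal(unname(sm$beta_fun(1e6)), sm$brody$A, tolerance = 1e-8)
  expect_error(smooth_params(classes[1:4, ]), ">= 5")
})

test_that("gamma thresholds match closed forms and an inverse-CDF oracle", {
  exp_fit <- structure(list(n = 10, s = 1, alpha = 1, beta = 1, mean = 1),
                       class = "gamma_fit")
  t1 <- gamma_thresholds(exp_fit, n_tests = 1)
  expect_equal(t1$cutoff, -log(0.05), tolerance = 1e-9)
  t20 <- gamma_thresholds(exp_fit, n_tests = 20)
  expect_gt(t20$cutoff, t1$cutoff)
  # monotone in n_tests
  cuts <- vapply(c(1, 10, 100, 1e4, 1e6), function(nt) {
    gamma_thresholds(exp_fit, nt)$cutoff
  }, numeric(1))
  expect_true(all(diff(cuts) > 0))

  g23 <- structure(list(n = 10, s = 1, alpha = 2, beta = 3, mean = 2 / 3),
                   class = "gamma_fit")
  cut <- gamma_thresholds(g23, n_tests = 413355)$cutoff
  oracle <- uniroot(function(x) pgamma(x, shape = 2, rate = 3) -
                      (1 - 0.05 / 413355),
                    c(0, 100), tol = 1e-12)$root
  expect_equal(cut, oracle, tolerance = 1e-8)
})

test_that("significance calls respect the >= boundary and need a threshold per k", {
  thr <- data.frame(k = c(2L, 3L), alpha = 1, beta = 1, cutoff = c(0.5, 0.7))
  loci <- data.frame(k = c(2L, 2L, 3L), sigma2 = c(0.4999999, 0.5, 0.7))
  out <- call_significant(loci, thr)
  expect_identical(out$flagged, c(FALSE, TRUE, TRUE))
  expect_error(call_significant(data.frame(k = 4L, sigma2 = 1), thr),
               "allele count")
})

test_that("class fits + smoothing control false flags on a null scan", {
  # one null panel end to end: no QTL, so any flag is a false positive;
  # across the three analyses the family-wise rate should be ~5% per family
  cfg <- sim_config(n_individuals = 250, n_chromosomes = 1,
                    snps_per_chrom = 400, chrom_length_bp = 4e6,
                    n_contemporary_groups = 10, seed = 66)
  st <- simulate_study(cfg)
  rc <- run_config(window_sizes = c(1, 3), seed = 66)
  res <- suppressMessages(run_pipeline(rc, geno = st$geno, pheno = st$pheno))
  expect_lte(nrow(res$flagged), 1L)
})
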