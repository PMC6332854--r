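test_that("GRM is built from standardized genotypes with the expected structure", {
  # iid Bernoulli genotypes: unrelated samples in HWE
  set.seed(41)
  n <- 120; m <- 4000
  p <- runif(m, 0.1, 0.9)
  g <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  keep <- apply(g, 2, function(x) length(unique(x)) > 1)
  G <- compute_grm(g[, keep])
  expect_true(isSymmetric(G$mat, tol = 1e-12))
  expect_equal(mean(diag(G$mat)), 1, tolerance = 0.05)
  off <- G$mat[upper.tri(G$mat)]
  expect_lt(abs(mean(off)), 0.05)

  # two identical samples have off-diagonal equal to their diagonals
  g2 <- rbind(g[1, keep], g[1, keep], g[2:20, keep])
  keep2 <- apply(g2, 2, function(x) length(unique(x)) > 1)
  G2 <- compute_grm(g2[, keep2])
  expect_equal(G2$mat[1, 2], G2$mat[1, 1], tolerance = 1e-12)

  # permuting samples permutes rows/columns consistently
  perm <- sample(nrow(g))
  Gp <- compute_grm(g[perm, keep])
  expect_equal(unname(Gp$mat), unname(G$mat[perm, perm]), tolerance = 1e-12)

  expect_error(compute_grm(matrix(c(0L, 0L, 0L, 1L), 2, 2)), "monomorphic")
})

test_that("pre-adjustment with one CG and constant age subtracts the mean", {
  set.seed(42)
  y <- rnorm(30, 10)
  adj <- preadjust_phenotype(y, rep("a", 30), rep(691, 30), diag(30))
  expect_equal(adj, y - mean(y), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("planted CG offsets and age slope are recovered", {
  set.seed(43)
  n <- 500
  cg <- rep(c("a", "b"), each = n / 2)
  age <- rnorm(n, 691, 102)
  y <- 5.9 + ifelse(cg == "a", -0.5, 0.5) + 0.002 * (age - 691) + rnorm(n, 0, 1)
  adj <- preadjust_phenotype(y, cg, age, diag(n))
  fit <- attr(adj, "fit")
  ols <- lm(y ~ factor(cg) + age)
  # with Vg ~ 0 the GLS solution matches OLS closed form
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)
  expect_lt(abs(fit$beta[["cgb"]] - 1.0), 2 * fit$beta_se[["cgb"]])
  expect_lt(abs(fit$beta[["age"]] - 0.002), 2 * fit$beta_se[["age"]])
  expect_lt(abs(mean(adj)), 1e-8)
  expect_error(preadjust_phenotype(y, rep(c("a", "b", "c"), c(2, 2, n - 4)),
                                   age, diag(n)),
               "fewer than 3")
})

test_that("identity GRM is flagged as unidentifiable", {
  set.seed(44)
  expect_warning(fit_null(rnorm(40), diag(40)), "identifiable")
})

test_that("variance components scale quadratically with the trait", {
  g <- small_panel(seed = 45, n = 150, snps = 300)
  G <- compute_grm(g)
  set.seed(45)
  L <- t(chol(G$mat + diag(1e-6, 150)))
  y <- as.numeric(L %*% rnorm(150)) + rnorm(150, 0, 1.2)
  f1 <- fit_null(y, G)
  f2 <- fit_null(3 * y, G)
  expect_equal(f2$Vg, 9 * f1$Vg, tolerance = 1e-3)
  expect_equal(f2$Ve, 9 * f1$Ve, tolerance = 1e-3)
  expect_equal(f2$lambda, f1$lambda, tolerance = 1e-3)
})

test_that("heritability is recovered in simulation", {
  errs <- vapply(1:3, function(sd) {
    cfg <- sim_config(n_individuals = 300, n_chromosomes = 1,
                      snps_per_chrom = 1200, chrom_length_bp = 6e6,
                      h2_polygenic = 0.3, cg_effect_sd = 0, age_slope = 0,
                      n_contemporary_groups = 10, seed = 100 + sd)
    st <- simulate_study(cfg)
    G <- compute_grm(st$geno)
    f <- fit_null(st$pheno$wbsf_kg - mean(st$pheno$wbsf_kg), G)
    f$Vg / (f$Vg + f$Ve) - 0.3
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.15)
})

test_that("with an identity-like fit the predictor test reduces to OLS", {
  set.seed(46)
  n <- 80
  y <- rnorm(n)
  x <- rbinom(n, 2, 0.3)
  null <- suppressWarnings(fit_null(y, diag(n)))
  res <- test_predictors(x, null)
  ols <- summary(lm(y ~ x))$coefficients
  expect_equal(res$effect, ols["x", "Estimate"], tolerance = 1e-8)
  expect_equal(res$se, ols["x", "Std. Error"], tolerance = 1e-8)
})

test_that("allele swap flips the effect sign and keeps the p-value", {
  g <- small_panel(seed = 47, n = 100, snps = 80)
  G <- compute_grm(g)
  set.seed(47)
  y <- rnorm(100)
  null <- fit_null(y, G)
  x <- genotype_matrix(g)[, 5]
  r1 <- test_predictors(x, null)
  r2 <- test_predictors(2 - x, null)
  expect_equal(r1$effect, -r2$effect, tolerance = 1e-12)
  expect_equal(r1$se, r2$se, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("constant dosage predictors are skipped with a message", {
  set.seed(48)
  null <- suppressWarnings(fit_null(rnorm(30), diag(30)))
  x <- cbind(rep(1, 30), rbinom(30, 2, 0.5))
  expect_message(res <- test_predictors(x, null), "skipped")
  expect_true(is.na(res$effect[1]))
  expect_false(is.na(res$effect[2]))
})

test_that("a planted typed SNP is the top association on its chromosome", {
  hits <- 0L
  within_2se <- 0L
  for (sd in 1:10) {
    q <- qtl_spec("1", 1e6, "typed_snp", effect = 0.5,
                  causal_freq_target = 0.35)
    cfg <- sim_config(n_individuals = 500, n_chromosomes = 3,
                      snps_per_chrom = 300, chrom_length_bp = 3e6,
                      qtls = list(q), h2_polygenic = 0.15,
                      n_contemporary_groups = 10, seed = 200 + sd)
    st <- simulate_study(cfg)
    G <- compute_grm(st$geno)
    eig <- haploscan:::.eigen_grm(G)
    adj <- preadjust_phenotype(st$pheno$wbsf_kg, st$pheno$cg,
                               st$pheno$age_days, eig)
    null <- fit_null(adj, eig)
    chr1 <- st$geno$map$chrom == "1"
    gm <- genotype_matrix(st$geno)[, chr1]
    res <- test_predictors(gm, null)
    top <- which.min(res$p)
    causal_idx <- which(st$geno$map$pos[chr1] == 1e6)
    eff <- res$effect[causal_idx]
    # effect recovered within 2 SE (sign convention: alt allele dosage)
    if (abs(abs(eff) - 0.5) < 2 * res$se[causal_idx]) {
      within_2se <- within_2se + 1L
    }
    # the top marker is the causal SNP itself or a marker in LD with it
    if (abs(st$geno$map$pos[chr1][top] - 1e6) < 5e4 ||
        cor(gm[, top], gm[, causal_idx])^2 > 0.2) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 8L)
  expect_gte(within_2se, 8L)
})

test_that("exact per-predictor REML agrees with the lambda-reuse approximation", {
  g <- small_panel(seed = 49, n = 120, snps = 100)
  G <- compute_grm(g)
  set.seed(49)
  L <- t(chol(G$mat + diag(1e-6, 120)))
  y <- as.numeric(L %*% rnorm(120)) * 0.8 + rnorm(120)
  null <- fit_null(y, G)
  x <- genotype_matrix(g)[, 1:10]
  a <- test_predictors(x, null, exact = FALSE)
  b <- test_predictors(x, null, exact = TRUE)
  expect_equal(a$effect, b$effect, tolerance = 0.05)
  expect_equal(a$p, b$p, tolerance = 0.1)
})
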