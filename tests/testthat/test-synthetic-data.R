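test_that("generation is deterministic given the seed", {
  cfg <- sim_config(n_individuals = 60, n_chromosomes = 2, snps_per_chrom = 80,
                    chrom_length_bp = 1e6, n_contemporary_groups = 5, seed = 42)
  g1 <- generate_haplotypes(cfg)
  g2 <- generate_haplotypes(cfg)
  expect_identical(g1$hap, g2$hap)
  expect_identical(g1$map, g2$map)
  p1 <- simulate_phenotypes(g1, cfg)
  p2 <- simulate_phenotypes(g2, cfg)
  expect_identical(p1$pheno, p2$pheno)

  # and the files round-trip byte-identically
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulate_study(cfg, out_dir = d1)
  simulate_study(cfg, out_dir = d2)
  expect_identical(readLines(file.path(d1, "genotypes.vcf")),
                   readLines(file.path(d2, "genotypes.vcf")))
  expect_identical(readLines(file.path(d1, "phenotypes.tsv")),
                   readLines(file.path(d2, "phenotypes.tsv")))
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_individuals = 0), "n_individuals")
  expect_error(sim_config(snps_per_chrom = 0), "snps_per_chrom")
  expect_error(sim_config(switch_rate = 0), "switch_rate")
  expect_error(sim_config(n_founder_haplotypes = 1), "n_founder")
  expect_error(sim_config(h2_polygenic = 1.2), "h2_polygenic")
})

test_that("no-recombination limit: every haplotype copies one founder, r2 = 1", {
  cfg <- sim_config(n_individuals = 40, n_chromosomes = 1, snps_per_chrom = 60,
                    chrom_length_bp = 1e6, n_founder_haplotypes = 2,
                    switch_rate = 1e-15, seed = 5)
  g <- generate_haplotypes(cfg)
  # with two founders and no switching, sample haplotypes take at most two
  # distinct values
  haps <- unique(apply(g$hap, 1, paste, collapse = ""))
  expect_lte(length(haps), 2L)
  # all polymorphic sites are perfectly correlated
  m <- ncol(g$hap)
  if (m >= 2) {
    for (j in 2:min(m, 6)) {
      expect_equal(pairwise_r2(g, 1, j), 1, tolerance = 1e-12)
    }
  }
})

test_that("high switch rate gives near-independent distant markers", {
  cfg <- sim_config(n_individuals = 150, n_chromosomes = 1,
                    snps_per_chrom = 100, chrom_length_bp = 1e6,
                    switch_rate = 0.5, seed = 6)
  g <- generate_haplotypes(cfg)
  dc <- decay_curve(g, max_dist = 1e6, bin_width = 2e5)
  far <- dc$mean_r2[dc$bin_start >= 2e5 & dc$n_pairs > 50]
  # E[r2] for independent sites is ~ 1/(2n) = 0.0033
  expect_true(all(far < 0.03))
})

test_that("frozen default config has the target LD decay regime", {
  cfg <- sim_config(seed = 1)
  g <- generate_haplotypes(cfg)
  dc <- decay_curve(g, max_dist = 1e6, bin_width = 5e4)
  beyond <- dc[dc$bin_start >= 1e5 & dc$n_pairs > 100, ]
  expect_true(all(beyond$mean_r2 < 0.15))
  # non-increasing in distance up to sampling noise
  mr <- dc$mean_r2[dc$n_pairs > 100]
  expect_true(all(diff(mr) < 0.02))
  # and short-range LD is appreciably stronger than the long-range tail
  expect_gt(dc$mean_r2[1], 2 * beyond$mean_r2[1])
})

test_that("null trait is iid normal at the configured mean and SD", {
  cfg <- sim_config(n_individuals = 500, n_chromosomes = 1,
                    snps_per_chrom = 150, chrom_length_bp = 2e6,
                    cg_effect_sd = 0, age_slope = 0, h2_polygenic = 0,
                    n_contemporary_groups = 10, seed = 9)
  g <- generate_haplotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  y <- ph$pheno$wbsf_kg
  expect_equal(mean(y), 5.9, tolerance = 0.15)
  expect_equal(sd(y), 1.80, tolerance = 0.15)
  # within-CG variance approaches trait_sd^2 (10% tolerance at this n)
  within <- tapply(y, ph$pheno$cg, var)
  expect_equal(mean(within), 1.80^2, tolerance = 0.10 * 1.80^2)
  expect_equal(shapiro.test(y)$p.value > 1e-4, TRUE)
})

test_that("typed-SNP QTL contributes 2p(1-p)a^2 and is emitted in the map", {
  q <- qtl_spec("1", 1e6, "typed_snp", effect = 0.5, causal_freq_target = 0.2)
  cfg <- sim_config(n_individuals = 600, n_chromosomes = 1,
                    snps_per_chrom = 100, chrom_length_bp = 2e6,
                    qtls = list(q), h2_polygenic = 0.2,
                    n_contemporary_groups = 10, seed = 10)
  g <- generate_haplotypes(cfg)
  expect_true(any(g$map$pos == 1e6))
  ph <- simulate_phenotypes(g, cfg)
  tq <- ph$truth$qtl
  p <- tq$realized_freq
  expect_equal(tq$realized_var, 2 * p * (1 - p) * 0.25, tolerance = 0.10)
  # realized dosage variance matches the HWE expectation 2p(1-p)
  dos <- genotype_matrix(g)[, g$map$pos == 1e6]
  expect_equal(var(dos), 2 * p * (1 - p), tolerance = 0.1)
  expect_true(all(ph$truth$qtl$realized_var >= 0))
})

test_that("untyped QTL is withheld from the map but drives the trait", {
  q <- qtl_spec("1", 1e6, "untyped_tagged", effect = 0.5,
                causal_freq_target = 0.2)
  cfg <- sim_config(n_individuals = 200, n_chromosomes = 1,
                    snps_per_chrom = 100, chrom_length_bp = 2e6,
                    qtls = list(q), n_contemporary_groups = 8, seed = 12)
  g <- generate_haplotypes(cfg)
  expect_false(any(g$map$pos == 1e6))
  ph <- simulate_phenotypes(g, cfg)
  expect_gt(ph$truth$qtl$realized_var, 0.02)
})

test_that("untyped QTL with no typed SNP within 100 kb is an error", {
  g <- toy_geno(matrix(rep(c(0L, 1L), 30), nrow = 6), pos = c(1e6, 1.001e6,
                                                              1.002e6, 1.003e6,
                                                              1.004e6, 1.005e6,
                                                              1.006e6, 1.007e6,
                                                              1.008e6, 1.009e6))
  q <- qtl_spec("1", 5e6, "untyped_tagged", effect = 0.5)
  attr(g, "causal") <- list(
    info = data.frame(chrom = "1", pos = 5e6, mode = "untyped_tagged",
                      effect = 0.5, target_freq = 0.2, realized_freq = 0.2,
                      typed_id = NA_character_, stringsAsFactors = FALSE),
    hap = matrix(rep(c(0L, 1L), 3), ncol = 1)
  )
  cfg <- sim_config(n_individuals = 3, n_chromosomes = 1, snps_per_chrom = 10,
                    chrom_length_bp = 6e6, qtls = list(q),
                    n_contemporary_groups = 1, h2_polygenic = 0, seed = 1)
  expect_error(simulate_phenotypes(g, cfg), "100 kb")
})
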