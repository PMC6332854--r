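#' Specification of one planted QTL
#'
#' @param chrom Chromosome id (matching the simulated map).
#' @param pos Position in bp of the causal site.
#' @param mode `"typed_snp"` (causal site is emitted as an ordinary SNP) or
#'   `"untyped_tagged"` (causal site is simulated, used for the phenotype, and
#'   then withheld from the emitted panel so it can only be tagged by
#'   haplotypes of flanking SNPs).
#' @param effect Allele substitution effect in kg per copy of the causal
#'   allele.
#' @param causal_freq_target Target frequency of the causal allele among
#'   founder haplotypes.
#' @return A list of class `qtl_spec`.
#' @export
qtl_spec <- function(chrom, pos, mode = c("typed_snp", "untyped_tagged"),
                     effect, causal_freq_target = 0.2) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(pos), pos >= 1,
            is.numeric(effect),
            causal_freq_target > 0, causal_freq_target < 1)
  structure(list(chrom = chrom, pos = as.integer(pos), mode = mode,
                 effect = effect, causal_freq_target = causal_freq_target),
            class = "qtl_spec")
}

#' Simulation configuration
#'
#' Defaults emulate a beef-cattle GWAS population: a Warner-Bratzler shear
#' force trait with mean 5.9 kg and SD 1.80 kg, contemporary-group fixed
#' effects, slaughter ages of 691 +/- 102 days entering as a linear covariate,
#' a polygenic background, and a dense SNP map whose linkage disequilibrium
#' decays below r^2 ~ 0.15 beyond 100 kb.
#'
#' Haplotypes are produced by a founder-copying model: each sample haplotype
#' is a mosaic of `n_founder_haplotypes` founder templates, switching template
#' with probability `switch_rate` per bp (so the expected copied segment
#' length is `1/switch_rate` bp). The default `switch_rate` was calibrated
#' once against the target decay regime and then frozen.
#'
#' @param n_individuals Number of diploid individuals.
#' @param n_chromosomes Number of autosomes to simulate.
#' @param snps_per_chrom Number of candidate SNP sites per chromosome (sites
#'   failing `maf_floor` after simulation are dropped, so the emitted count
#'   can be slightly smaller).
#' @param chrom_length_bp Chromosome length in bp.
#' @param n_founder_haplotypes Number of founder templates (>= 2).
#' @param switch_rate Per-bp probability of switching the copied template.
#' @param maf_floor Minimum minor-allele frequency of emitted SNPs.
#' @param n_contemporary_groups Number of contemporary groups (CG).
#' @param cg_effect_sd SD of the CG fixed effects, kg.
#' @param age_mean,age_sd Age at slaughter, days (normal, truncated at 3 SD).
#' @param age_slope Linear age effect, kg per day.
#' @param h2_polygenic Proportion of `trait_sd^2` given to the polygenic term.
#' @param trait_mean,trait_sd Trait mean and SD, kg.
#' @param qtls List of [qtl_spec()] objects.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 500L,
                       n_chromosomes = 2L,
                       snps_per_chrom = 1000L,
                       chrom_length_bp = 10e6,
                       n_founder_haplotypes = 50L,
                       switch_rate = 2e-6,
                       maf_floor = 0.05,
                       n_contemporary_groups = 20L,
                       cg_effect_sd = 0.5,
                       age_mean = 691,
                       age_sd = 102,
                       age_slope = 0.002,
                       h2_polygenic = 0.25,
                       trait_mean = 5.9,
                       trait_sd = 1.80,
                       qtls = list(),
                       seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_chromosomes = as.integer(n_chromosomes),
    snps_per_chrom = as.integer(snps_per_chrom),
    chrom_length_bp = chrom_length_bp,
    n_founder_haplotypes = as.integer(n_founder_haplotypes),
    switch_rate = switch_rate,
    maf_floor = maf_floor,
    n_contemporary_groups = as.integer(n_contemporary_groups),
    cg_effect_sd = cg_effect_sd,
    age_mean = age_mean, age_sd = age_sd, age_slope = age_slope,
    h2_polygenic = h2_polygenic,
    trait_mean = trait_mean, trait_sd = trait_sd,
    qtls = qtls, seed = as.integer(seed)
  )
  if (cfg$n_individuals < 1L) stop("n_individuals must be >= 1")
  if (cfg$n_chromosomes < 1L) stop("n_chromosomes must be >= 1")
  if (cfg$snps_per_chrom < 1L) stop("snps_per_chrom must be >= 1")
  if (cfg$n_founder_haplotypes < 2L) stop("n_founder_haplotypes must be >= 2")
  if (!(cfg$switch_rate > 0)) stop("switch_rate must be > 0")
  if (cfg$maf_floor < 0 || cfg$maf_floor > 0.5) {
    stop("maf_floor must be in [0, 0.5]")
  }
  if (cfg$h2_polygenic < 0 || cfg$h2_polygenic > 1) {
    stop("h2_polygenic must be in [0, 1]")
  }
  if (cfg$trait_sd <= 0) stop("trait_sd must be > 0")
  for (q in cfg$qtls) {
    if (!inherits(q, "qtl_spec")) stop("qtls must be a list of qtl_spec objects")
    if (!(q$chrom %in% paste0("chr", seq_len(cfg$n_chromosomes))) &&
        !(q$chrom %in% seq_len(cfg$n_chromosomes))) {
      stop("QTL chromosome ", q$chrom, " outside the simulated genome")
    }
    if (q$pos < 1 || q$pos > cfg$chrom_length_bp) {
      stop("QTL position ", q$pos, " outside chromosome bounds")
    }
  }
  structure(cfg, class = "sim_config")
}
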