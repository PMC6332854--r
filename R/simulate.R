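# Founder-copying simulator of phased genotypes and of phenotypes with the
# fixed/random structure the association model assumes.

# Internal: number of ancestral templates the founder haplotypes are mosaics
# of. Founders built from a small ancestral pool carry internal LD, which the
# sample haplotypes then inherit; with iid founder alleles the short-range
# r^2 plateau would be ~1/n_founders and far below what dense cattle panels
# show.
.n_ancestral <- 6L
.founder_flip_rate <- 0.01

# Copy rows out of a template matrix, switching the copied template between
# consecutive sites with probability 1 - exp(-rate * gap).
.mosaic <- function(templates, n_out, pos, rate) {
  m <- length(pos)
  k <- nrow(templates)
  q <- 1 - exp(-rate * diff(pos))
  out <- matrix(0L, n_out, m)
  for (r in seq_len(n_out)) {
    sw <- c(TRUE, stats::runif(m - 1L) < q)
    seg <- cumsum(sw)
    tmpl <- sample.int(k, seg[m], replace = TRUE)
    out[r, ] <- templates[cbind(tmpl[seg], seq_len(m))]
  }
  out
}

#' Generate phased genotypes under a founder-copying model
#'
#' Each of the `2 * n_individuals` sample haplotypes is a mosaic of
#' `n_founder_haplotypes` founder templates, switching template with per-bp
#' probability `switch_rate`; the founders themselves are mosaics of a small
#' ancestral pool, which gives the panel realistic short-range linkage
#' disequilibrium that decays with distance. Sites whose realized minor
#' allele frequency falls below `maf_floor` are dropped. Causal sites for the
#' configured QTLs are simulated jointly with the panel; sites of
#' `untyped_tagged` QTLs are withheld from the emitted map and kept only in a
#' hidden attribute consumed by [simulate_phenotypes()].
#'
#' @param config A [sim_config()].
#' @return A [phased_genotypes()] object (with a `causal` attribute when QTLs
#'   are configured).
#' @export
generate_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  nh <- 2L * n
  K <- cfg$n_founder_haplotypes

  maps <- list()
  haps <- list()
  causal_info <- list()
  causal_hap <- list()

  for (ch in seq_len(cfg$n_chromosomes)) {
    chrom <- as.character(ch)
    n_cand <- ceiling(cfg$snps_per_chrom * 1.5)
    pos <- sort(sample.int(cfg$chrom_length_bp, n_cand))
    qtls <- Filter(function(q) as.character(q$chrom) == chrom, cfg$qtls)
    qpos <- vapply(qtls, function(q) q$pos, integer(1))
    pos <- sort(unique(c(pos, qpos)))
    m <- length(pos)
    is_causal <- pos %in% qpos

    # ancestral pool -> founders (with a little site-level noise so founders
    # stay distinct) -> sample haplotypes
    p_site <- stats::runif(m, 0.1, 0.9)
    anc <- matrix(stats::rbinom(.n_ancestral * m, 1L, rep(p_site, each = .n_ancestral)),
                  nrow = .n_ancestral)
    # causal sites segregate on the ancestral genealogy like any other
    # variant (that is what lets flanking haplotypes tag them); the number
    # of carrier ancestors approximates the target frequency
    for (q in qtls) {
      j <- match(q$pos, pos)
      nc <- max(1L, min(.n_ancestral - 1L,
                        round(q$causal_freq_target * .n_ancestral)))
      anc[, j] <- 0L
      anc[sample.int(.n_ancestral, nc), j] <- 1L
    }
    founders <- .mosaic(anc, K, pos, cfg$switch_rate)
    flip <- matrix(stats::runif(K * m) < .founder_flip_rate, K, m)
    founders <- abs(founders - flip)
    hap <- .mosaic(founders, nh, pos, cfg$switch_rate)

    f <- colMeans(hap)
    maf <- pmin(f, 1 - f)
    keep <- maf >= cfg$maf_floor & !is_causal
    # cap the emitted count at the configured sites-per-chromosome
    keep_idx <- which(keep)
    if (length(keep_idx) > cfg$snps_per_chrom) {
      # thin evenly along the chromosome rather than truncating it
      sel <- round(seq(1, length(keep_idx), length.out = cfg$snps_per_chrom))
      keep_idx <- keep_idx[sel]
    }
    emit <- rep(FALSE, m)
    emit[keep_idx] <- TRUE
    # typed causal sites are always emitted (their frequency is pinned by
    # design, not subject to the panel MAF floor)
    for (q in qtls) {
      j <- match(q$pos, pos)
      cid <- paste0("snp_", chrom, "_", pos[j])
      if (q$mode == "typed_snp") emit[j] <- TRUE
      causal_info[[length(causal_info) + 1L]] <- data.frame(
        chrom = chrom, pos = q$pos, mode = q$mode, effect = q$effect,
        target_freq = q$causal_freq_target, realized_freq = f[j],
        typed_id = if (q$mode == "typed_snp") cid else NA_character_,
        stringsAsFactors = FALSE
      )
      causal_hap[[length(causal_hap) + 1L]] <- hap[, j]
    }

    alle <- matrix(c("A", "C", "G", "T")[
      t(replicate(sum(emit), sample.int(4L, 2L)))], ncol = 2L)
    maps[[ch]] <- data.frame(
      chrom = chrom, pos = pos[emit],
      id = paste0("snp_", chrom, "_", pos[emit]),
      ref = alle[, 1L], alt = alle[, 2L],
      stringsAsFactors = FALSE
    )
    haps[[ch]] <- hap[, emit, drop = FALSE]
  }

  map <- do.call(rbind, maps)
  if (nrow(map) == 0L) stop("no SNPs survived the MAF floor; degenerate config")
  geno <- phased_genotypes(
    samples = sprintf("ind%04d", seq_len(n)),
    map = map,
    hap = do.call(cbind, haps)
  )
  if (length(causal_info) > 0L) {
    attr(geno, "causal") <- list(
      info = do.call(rbind, causal_info),
      hap = do.call(cbind, causal_hap)
    )
  }
  geno
}

#' Simulate phenotypes over a generated panel
#'
#' Builds `y = mean + CG effect + age_slope * (age - age_mean) + QTL effects +
#' polygenic + residual`. The polygenic values are drawn with covariance
#' proportional to the realized standardized-genotype relationship matrix
#' (plus a 1e-6 diagonal jitter), scaled to `h2_polygenic * trait_sd^2`; the
#' residual variance is `trait_sd^2 * (1 - h2_polygenic)` minus the realized
#' QTL variance, so the within-group trait variance lands near `trait_sd^2`.
#' QTL dosage contributions are centred, leaving the trait mean at
#' `trait_mean`.
#'
#' @param geno Panel from [generate_haplotypes()].
#' @param config The same [sim_config()] used to generate it.
#' @return A list with `pheno` (data frame: `id`, `wbsf_kg`, `cg`,
#'   `age_days`) and `truth` (a `truth_table`: per-QTL realized frequencies
#'   and variance contributions, per-individual latent components).
#' @export
simulate_phenotypes <- function(geno, config) {
  stopifnot(inherits(geno, "phased_geno"), inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed + 1L)
  n <- length(geno$samples)
  G <- cfg$n_contemporary_groups
  if (n < 3L * G) {
    stop("need at least 3 individuals per contemporary group (n = ", n,
         ", groups = ", G, ")")
  }
  cg <- sample(rep_len(seq_len(G), n))
  cg_eff <- stats::rnorm(G, 0, cfg$cg_effect_sd)
  age <- stats::rnorm(n, cfg$age_mean, cfg$age_sd)
  out3 <- abs(age - cfg$age_mean) > 3 * cfg$age_sd
  while (any(out3)) {
    age[out3] <- stats::rnorm(sum(out3), cfg$age_mean, cfg$age_sd)
    out3 <- abs(age - cfg$age_mean) > 3 * cfg$age_sd
  }

  causal <- attr(geno, "causal")
  if (length(cfg$qtls) > 0L && is.null(causal)) {
    stop("config declares QTLs but the panel carries no causal sites; ",
         "generate the panel with the same config")
  }
  qtl_y <- numeric(n)
  qtl_var <- numeric(0)
  truth_qtl <- NULL
  if (!is.null(causal)) {
    info <- causal$info
    for (i in seq_len(nrow(info))) {
      if (info$mode[i] == "untyped_tagged") {
        near <- geno$map$chrom == info$chrom[i] &
          abs(geno$map$pos - info$pos[i]) <= 1e5
        if (!any(near)) {
          stop("untyped_tagged QTL at ", info$chrom[i], ":", info$pos[i],
               " has no typed SNP within 100 kb; tagging impossible")
        }
      }
      hp <- causal$hap[, i]
      dos <- hp[seq(1L, 2L * n, 2L)] + hp[seq(2L, 2L * n, 2L)]
      contrib <- info$effect[i] * (dos - mean(dos))
      qtl_y <- qtl_y + contrib
      qtl_var <- c(qtl_var, stats::var(contrib))
    }
    truth_qtl <- cbind(info, realized_var = qtl_var)
  }

  sigma_g2 <- cfg$h2_polygenic * cfg$trait_sd^2
  g <- numeric(n)
  if (cfg$h2_polygenic > 0) {
    grm <- compute_grm(geno)
    L <- t(chol(grm$mat + diag(1e-6, n)))
    g <- as.numeric(L %*% stats::rnorm(n)) * sqrt(sigma_g2)
  }
  ve <- cfg$trait_sd^2 * (1 - cfg$h2_polygenic) - sum(qtl_var)
  if (ve <= 0) {
    stop("planted QTL variance (", round(sum(qtl_var), 3),
         ") exceeds the non-polygenic trait variance budget")
  }
  e <- stats::rnorm(n, 0, sqrt(ve))

  y <- cfg$trait_mean + cg_eff[cg] + cfg$age_slope * (age - cfg$age_mean) +
    qtl_y + g + e
  pheno <- data.frame(
    id = geno$samples,
    wbsf_kg = y,
    cg = sprintf("cg%02d", cg),
    age_days = age,
    stringsAsFactors = FALSE
  )
  truth <- structure(list(
    qtl = truth_qtl,
    indiv = data.frame(id = geno$samples, cg = pheno$cg, age_days = age,
                       polygenic = g, residual = e,
                       stringsAsFactors = FALSE),
    residual_var = ve, polygenic_var = sigma_g2
  ), class = "truth_table")
  list(pheno = pheno, truth = truth)
}

#' Simulate a complete study (genotypes + phenotypes)
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `genotypes.vcf`,
#'   `phenotypes.tsv` and `truth_qtl.tsv` there.
#' @return List with `geno`, `pheno`, `truth`.
#' @export
simulate_study <- function(config, out_dir = NULL) {
  geno <- generate_haplotypes(config)
  ph <- simulate_phenotypes(geno, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_phased_vcf(geno, file.path(out_dir, "genotypes.vcf"))
    utils::write.table(ph$pheno, file.path(out_dir, "phenotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(ph$truth$qtl)) {
      utils::write.table(ph$truth$qtl, file.path(out_dir, "truth_qtl.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    message("simulated study written to ", out_dir,
            " (seed ", config$seed, ")")
  }
  list(geno = geno, pheno = ph$pheno, truth = ph$truth)
}
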