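# End-to-end pipeline: QC -> GRM -> phenotype pre-adjustment -> per-window
# association -> per-locus variances -> gamma thresholds -> significant loci
# -> QTL regions and LD summaries.

#' Pipeline configuration
#'
#' @param vcf,pheno Input paths (phased VCF, phenotype TSV with columns
#'   `id`, `wbsf_kg`, `cg`, `age_days`), or `NULL` when objects are passed
#'   to [run_pipeline()] directly.
#' @param out_dir Output directory (`NULL`: nothing written).
#' @param window_sizes Analyses to run; 1 means single-SNP (default
#'   `c(1, 3, 5, 7, 9, 11)`).
#' @param sample_cr,marker_cr,maf_min,hwe_p_min QC thresholds.
#' @param autosomes Accepted chromosome labels (`NULL`: all).
#' @param exact Exact per-predictor REML instead of reusing the null-model
#'   variance ratio.
#' @param variance_scale `"as_printed"` or `"snp_consistent"` (see
#'   [haplotype_variance()]).
#' @param pool_rare Pool haplotype alleles seen on < 2 copies.
#' @param smooth_thresholds Smooth gamma parameters over allele counts when
#'   >= 5 classes are available (default `TRUE`).
#' @param family_alpha Family-wise error level for the Bonferroni-corrected
#'   gamma quantiles (default 0.05).
#' @param ld_max_dist,ld_bin_width Decay-curve bins (bp).
#' @param seed Seed for any subsampling (logged).
#' @return A `run_config` list.
#' @export
run_config <- function(vcf = NULL, pheno = NULL, out_dir = NULL,
                       window_sizes = c(1, 3, 5, 7, 9, 11),
                       sample_cr = 0.90, marker_cr = 0.95,
                       maf_min = 0.05, hwe_p_min = 1e-5, autosomes = NULL,
                       exact = FALSE,
                       variance_scale = c("as_printed", "snp_consistent"),
                       pool_rare = FALSE, smooth_thresholds = TRUE,
                       family_alpha = 0.05,
                       ld_max_dist = 1e6, ld_bin_width = 5e4, seed = 1L) {
  variance_scale <- match.arg(variance_scale)
  if (any(window_sizes %% 2 == 0) || any(window_sizes < 1)) {
    stop("window sizes must be odd and >= 1")
  }
  if (family_alpha <= 0 || family_alpha >= 1) {
    stop("family_alpha must be in (0, 1)")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

.write_tsv <- function(x, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full association pipeline
#'
#' Stages: QC, GRM, phenotype pre-adjustment (contemporary group + age),
#' per-window-size association scans, per-locus additive variances, gamma
#' threshold fitting, significance calls, QTL-region merging, and LD
#' summaries. Every stage's output is persisted as TSV when `out_dir` is
#' set; counts and seeds are logged via messages.
#'
#' @param config A `run_config` (or path to a YAML file).
#' @param geno,pheno Optional in-memory inputs overriding the configured
#'   paths: a [phased_genotypes()] panel and a phenotype data frame.
#' @return List with `qc`, `null`, per-analysis `scans` (assoc, loci,
#'   thresholds), `flagged`, `regions`, `detection`, `decay`.
#' @export
run_pipeline <- function(config, geno = NULL, pheno = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  }

  if (is.null(geno)) {
    geno <- .stage("load_genotypes", read_phased_vcf(cfg$vcf))
  }
  if (is.null(pheno)) {
    pheno <- .stage("load_phenotypes",
                    utils::read.delim(cfg$pheno, stringsAsFactors = FALSE))
  }
  need <- c("id", "wbsf_kg", "cg", "age_days")
  if (!all(need %in% names(pheno))) {
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  }

  qc <- .stage("qc", apply_qc(geno, sample_cr = cfg$sample_cr,
                              marker_cr = cfg$marker_cr,
                              maf_min = cfg$maf_min,
                              hwe_p_min = cfg$hwe_p_min,
                              autosomes = cfg$autosomes))
  geno <- qc$geno
  message("QC: ", attr(qc$report, "retained_samples"), " samples, ",
          attr(qc$report, "retained_markers"), " markers retained")
  .write_tsv(cbind(qc$report), cfg$out_dir, "qc_report.tsv")

  m <- match(geno$samples, pheno$id)
  if (anyNA(m)) stop("phenotypes missing for sample(s): ",
                     paste(utils::head(geno$samples[is.na(m)]), collapse = ", "))
  pheno <- pheno[m, , drop = FALSE]

  grm <- .stage("grm", compute_grm(geno))
  eig <- .stage("grm_eigen", .eigen_grm(grm))
  y_adj <- .stage("preadjust",
                  preadjust_phenotype(pheno$wbsf_kg, pheno$cg,
                                      pheno$age_days, eig))
  null <- .stage("null_model", fit_null(y_adj, eig))
  message("null model: Vg = ", signif(null$Vg, 4), ", Ve = ",
          signif(null$Ve, 4))

  scans <- list()
  flagged <- list()
  for (w in sort(cfg$window_sizes)) {
    an <- if (w == 1) "SNP" else paste0("SW", w)
    assoc <- .stage(paste0("assoc_", an),
                    assoc_scan(geno, y_adj, null, w, exact = cfg$exact,
                               pool_rare = cfg$pool_rare))
    loci <- .stage(paste0("variance_", an),
                   locus_variances(assoc, scale = cfg$variance_scale,
                                   snp_formula = (w == 1)))
    n_tests <- nrow(loci)
    thr <- .stage(paste0("thresholds_", an), {
      if (w == 1) {
        x <- loci$sigma2[!is.na(loci$sigma2) & loci$sigma2 > 0]
        fit <- fit_gamma_mom(x)
        gamma_thresholds(fit, n_tests, level = cfg$family_alpha)
      } else {
        classes <- suppressMessages(fit_gamma_classes(loci))
        ks <- sort(unique(loci$k))
        if (cfg$smooth_thresholds && nrow(classes) >= 5L) {
          sm <- smooth_params(classes)
          gamma_thresholds(sm, n_tests, level = cfg$family_alpha, k = ks)
        } else {
          tt <- gamma_thresholds(classes, n_tests, level = cfg$family_alpha)
          # classes too small to fit borrow the nearest fitted class
          missing_k <- setdiff(ks, tt$k)
          if (length(missing_k)) {
            nearest <- vapply(missing_k, function(kk) {
              tt$k[which.min(abs(tt$k - kk))]
            }, numeric(1))
            add <- tt[match(nearest, tt$k), , drop = FALSE]
            add$k <- missing_k
            tt <- rbind(tt, add)
            message(an, ": ", length(missing_k), " allele-count class(es) ",
                    "borrowed the nearest fitted class threshold")
          }
          tt[order(tt$k), , drop = FALSE]
        }
      }
    })
    called <- .stage(paste0("flags_", an), call_significant(loci, thr))
    nf <- sum(called$flagged)
    message(an, ": ", n_tests, " loci tested, ", nf, " flagged")
    scans[[an]] <- list(assoc = assoc, loci = called, thresholds = thr)
    if (nf > 0) {
      fl <- called[called$flagged, , drop = FALSE]
      fl$analysis <- an
      fl$sigma2 <- fl$sigma2
      flagged[[an]] <- fl[, c("chrom", "start_bp", "end_bp", "first_id",
                              "last_id", "sigma2", "analysis")]
    }
    .write_tsv(assoc, cfg$out_dir, paste0("assoc_", an, ".tsv"))
    .write_tsv(called, cfg$out_dir, paste0("loci_", an, ".tsv"))
    .write_tsv(thr, cfg$out_dir, paste0("thresholds_", an, ".tsv"))
  }

  flagged_all <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(chrom = character(), start_bp = integer(),
               end_bp = integer(), first_id = character(),
               last_id = character(), sigma2 = numeric(),
               analysis = character(), stringsAsFactors = FALSE)
  rownames(flagged_all) <- NULL
  regions <- .stage("regions", merge_regions(flagged_all, geno = geno))
  detection <- if (nrow(regions) > 0) detection_summary(regions) else NULL
  decay <- .stage("ld_decay",
                  decay_curve(geno, max_dist = cfg$ld_max_dist,
                              bin_width = cfg$ld_bin_width,
                              seed = cfg$seed))
  message("regions: ", nrow(regions), " (seed ", cfg$seed, ")")
  if (!is.null(cfg$out_dir)) {
    .write_tsv(flagged_all, cfg$out_dir, "flagged_loci.tsv")
    .write_tsv(regions, cfg$out_dir, "qtl_regions.tsv")
    if (nrow(regions) > 0) {
      write_regions_bed(regions, file.path(cfg$out_dir, "qtl_regions.bed"))
    }
    if (!is.null(detection)) {
      .write_tsv(detection, cfg$out_dir, "detection_summary.tsv")
    }
    .write_tsv(decay, cfg$out_dir, "ld_decay.tsv")
  }
  list(qc = qc$report, grm = grm, null = null, y_adj = y_adj,
       scans = scans, flagged = flagged_all, regions = regions,
       detection = detection, decay = decay)
}
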