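# Marker and sample quality control mirroring standard SNP-array filters:
# sample call rate, then marker call rate, minor allele frequency and
# Hardy-Weinberg equilibrium, in that order.

#' Hardy-Weinberg equilibrium chi-square p-values
#'
#' One-degree-of-freedom chi-square test of the observed genotype counts
#' against the counts expected from the allele frequencies. Missing genotypes
#' are excluded.
#'
#' @param geno A [phased_genotypes()] object.
#' @return Numeric vector of p-values, one per marker (NA for monomorphic
#'   markers, which cannot deviate from HWE).
#' @export
hwe_pvalues <- function(geno) {
  g <- genotype_matrix(geno)
  m <- ncol(g)
  p <- numeric(m)
  for (j in seq_len(m)) {
    gj <- g[, j]
    gj <- gj[!is.na(gj)]
    nobs <- length(gj)
    n0 <- sum(gj == 0L); n1 <- sum(gj == 1L); n2 <- sum(gj == 2L)
    q <- (n1 + 2 * n2) / (2 * nobs)
    if (nobs == 0L || q <= 0 || q >= 1) {
      p[j] <- NA_real_
      next
    }
    e <- nobs * c((1 - q)^2, 2 * q * (1 - q), q^2)
    x2 <- sum((c(n0, n1, n2) - e)^2 / e)
    p[j] <- stats::pchisq(x2, df = 1, lower.tail = FALSE)
  }
  p
}

#' Apply marker and sample quality filters
#'
#' Samples with call rate below `sample_cr` are removed first; then markers
#' failing call rate, minor allele frequency (computed after sample removal,
#' missing alleles excluded from denominators), or the HWE chi-square test
#' are removed. Boundary values are kept: the filters remove strictly-below
#' thresholds (a marker with MAF exactly 0.05 is retained).
#'
#' @param geno A [phased_genotypes()] object.
#' @param sample_cr Minimum sample call rate (default 0.90).
#' @param marker_cr Minimum marker call rate (default 0.95).
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param hwe_p_min Minimum HWE test p-value (default 1e-5).
#' @param autosomes Optional character vector of accepted (autosomal)
#'   chromosome labels; markers on other chromosomes are removed. `NULL`
#'   keeps all chromosomes.
#' @return List with `geno` (filtered panel) and `report` (a `qc_report`
#'   data frame itemizing removals per filter, in application order).
#' @export
apply_qc <- function(geno, sample_cr = 0.90, marker_cr = 0.95,
                     maf_min = 0.05, hwe_p_min = 1e-5, autosomes = NULL) {
  stopifnot(inherits(geno, "phased_geno"))
  if (nrow(geno$map) == 0L || length(geno$samples) == 0L) {
    stop("empty genotype panel")
  }
  n0_samples <- length(geno$samples)
  n0_markers <- nrow(geno$map)
  steps <- list()

  # 1. chromosome filter (non-autosomal / unmapped markers)
  if (!is.null(autosomes)) {
    keep <- geno$map$chrom %in% autosomes
    steps[["marker_chromosome"]] <- sum(!keep)
    geno <- subset_geno(geno, variants = keep)
  } else {
    steps[["marker_chromosome"]] <- 0L
  }

  # 2. sample call rate
  n <- length(geno$samples)
  hap_by_sample <- geno$hap[seq(1L, 2L * n, 2L), , drop = FALSE]
  hap_by_sample2 <- geno$hap[seq(2L, 2L * n, 2L), , drop = FALSE]
  miss <- is.na(hap_by_sample) + is.na(hap_by_sample2)
  s_cr <- 1 - rowSums(miss) / (2 * ncol(geno$hap))
  keep_s <- s_cr >= sample_cr
  steps[["sample_call_rate"]] <- sum(!keep_s)
  geno <- subset_geno(geno, samples = keep_s)

  # 3. marker call rate
  m_cr <- 1 - colMeans(is.na(geno$hap))
  keep_cr <- m_cr >= marker_cr
  steps[["marker_call_rate"]] <- sum(!keep_cr)
  geno <- subset_geno(geno, variants = keep_cr)

  # 4. minor allele frequency (after sample removal - order matters)
  f <- allele_freq(geno)
  maf <- pmin(f, 1 - f)
  keep_maf <- maf >= maf_min
  steps[["marker_maf"]] <- sum(!keep_maf)
  geno <- subset_geno(geno, variants = keep_maf)

  # 5. Hardy-Weinberg equilibrium
  hwe <- hwe_pvalues(geno)
  keep_hwe <- is.na(hwe) | hwe >= hwe_p_min
  steps[["marker_hwe"]] <- sum(!keep_hwe)
  geno <- subset_geno(geno, variants = keep_hwe)

  if (nrow(geno$map) == 0L) stop("all markers removed by QC")

  report <- data.frame(
    filter = names(steps),
    threshold = c(if (is.null(autosomes)) NA_real_ else NA_real_,
                  sample_cr, marker_cr, maf_min, hwe_p_min),
    removed = unlist(steps, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  attr(report, "input_samples") <- n0_samples
  attr(report, "input_markers") <- n0_markers
  attr(report, "retained_samples") <- length(geno$samples)
  attr(report, "retained_markers") <- nrow(geno$map)
  class(report) <- c("qc_report", "data.frame")
  list(geno = geno, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", attr(x, "input_samples"), "samples /",
      attr(x, "input_markers"), "markers in;",
      attr(x, "retained_samples"), "/", attr(x, "retained_markers"),
      "retained\n")
  print.data.frame(x)
  invisible(x)
}
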