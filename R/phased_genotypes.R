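#' Phased genotype panel
#'
#' Container for a panel of phased diploid genotypes at biallelic SNPs.
#' Haplotypes are stored as a `(2 * n_samples) x n_variants` integer matrix of
#' reference/alternate allele codes (0/1, `NA` for missing); rows `2i - 1` and
#' `2i` are the two haplotypes of sample `i`, so phase is implicit in row
#' order.
#'
#' @param samples Character vector of sample ids.
#' @param map Data frame with one row per variant and columns `chrom`, `pos`
#'   (1-based bp, strictly increasing within chromosome), `id`, `ref`, `alt`.
#' @param hap Integer matrix of allele codes, `2 * length(samples)` rows.
#'
#' @return An object of class `phased_geno`.
#' @export
phased_genotypes <- function(samples, map, hap) {
  stopifnot(is.character(samples), is.data.frame(map), is.matrix(hap))
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(map))) {
    stop("variant map must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(hap) != 2L * length(samples)) {
    stop("hap matrix must have 2 rows per sample (got ", nrow(hap),
         " rows for ", length(samples), " samples)")
  }
  if (ncol(hap) != nrow(map)) {
    stop("hap matrix has ", ncol(hap), " columns but map has ",
         nrow(map), " variants")
  }
  bad <- !(hap %in% c(0L, 1L, NA_integer_))
  if (any(bad)) stop("allele codes must be 0, 1 or NA")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  structure(
    list(samples = samples, map = map, hap = hap),
    class = "phased_geno"
  )
}

#' @export
print.phased_geno <- function(x, ...) {
  cat("phased_geno:", length(x$samples), "samples,", nrow(x$map),
      "variants on", length(unique(x$map$chrom)), "chromosome(s)\n")
  if (!is.null(attr(x, "causal"))) {
    cat("  carries", ncol(attr(x, "causal")$hap), "hidden causal site(s)\n")
  }
  invisible(x)
}

#' @export
dim.phased_geno <- function(x) c(length(x$samples), nrow(x$map))

#' Sample-level genotype dosage matrix
#'
#' Collapses the two haplotypes of each sample into the usual 0/1/2 count of
#' the alternate allele.
#'
#' @param geno A [phased_genotypes()] object.
#' @return Integer matrix, samples x variants.
#' @export
genotype_matrix <- function(geno) {
  stopifnot(inherits(geno, "phased_geno"))
  n <- length(geno$samples)
  odd <- geno$hap[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  even <- geno$hap[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  g <- odd + even
  rownames(g) <- geno$samples
  colnames(g) <- geno$map$id
  g
}

#' Alternate-allele frequencies
#'
#' @param geno A [phased_genotypes()] object.
#' @return Numeric vector of alternate-allele frequencies, missing alleles
#'   excluded from the denominators.
#' @export
allele_freq <- function(geno) {
  stopifnot(inherits(geno, "phased_geno"))
  colMeans(geno$hap, na.rm = TRUE)
}

#' Subset a phased panel
#'
#' @param geno A [phased_genotypes()] object.
#' @param samples,variants Index vectors (integer or logical) over samples and
#'   variants; `NULL` keeps everything.
#' @return A new `phased_geno`.
#' @export
subset_geno <- function(geno, samples = NULL, variants = NULL) {
  stopifnot(inherits(geno, "phased_geno"))
  if (is.null(samples)) samples <- seq_along(geno$samples)
  if (is.logical(samples)) samples <- which(samples)
  if (is.null(variants)) variants <- seq_len(nrow(geno$map))
  hap_rows <- as.vector(rbind(2L * samples - 1L, 2L * samples))
  out <- phased_genotypes(
    samples = geno$samples[samples],
    map = geno$map[variants, , drop = FALSE],
    hap = geno$hap[hap_rows, variants, drop = FALSE]
  )
  ca <- attr(geno, "causal")
  if (!is.null(ca)) {
    ca$hap <- ca$hap[hap_rows, , drop = FALSE]
    attr(out, "causal") <- ca
  }
  out
}
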