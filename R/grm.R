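#' Genomic relationship matrix from standardized genotypes
#'
#' Each genotype column is centred by twice the alternate-allele frequency
#' and scaled by `1/sqrt(2 p (1 - p))`; the GRM is `G = W W' / m` over the
#' `m` markers. For a panel in Hardy-Weinberg equilibrium the mean diagonal
#' is close to 1 and off-diagonals of unrelated samples close to 0.
#'
#' @param geno A [phased_genotypes()] object or a samples x markers 0/1/2
#'   dosage matrix (no missing values, no monomorphic markers).
#' @return A `grm`: list with `mat` (n x n symmetric), `samples`, `m`.
#' @export
compute_grm <- function(geno) {
  if (inherits(geno, "phased_geno")) {
    g <- genotype_matrix(geno)
    samples <- geno$samples
  } else {
    g <- geno
    samples <- rownames(g)
    if (is.null(samples)) samples <- paste0("s", seq_len(nrow(g)))
  }
  if (anyNA(g)) stop("GRM requires complete genotypes (impute first)")
  p <- colMeans(g) / 2
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic marker(s) in GRM input: ",
         paste(utils::head(colnames(g)[p <= 0 | p >= 1]), collapse = ", "))
  }
  w <- sweep(g, 2, 2 * p, "-")
  w <- sweep(w, 2, sqrt(2 * p * (1 - p)), "/")
  mat <- tcrossprod(w) / ncol(g)
  dimnames(mat) <- list(samples, samples)
  structure(list(mat = mat, samples = samples, m = ncol(g)), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", length(x$samples), "samples from", x$m, "markers; mean diag =",
      round(mean(diag(x$mat)), 3), "\n")
  invisible(x)
}
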