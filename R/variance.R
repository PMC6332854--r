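# Additive genetic variance of single SNPs and multi-allelic haplotype loci.

#' Additive variance of a biallelic SNP
#'
#' `sigma^2 = 2 p (1 - p) a^2`, symmetric in `p <-> 1 - p` and invariant to
#' the sign of the substitution effect.
#'
#' @param p Allele frequency, strictly inside (0, 1).
#' @param a Allele substitution effect (kg).
#' @return Additive genetic variance (kg^2).
#' @export
snp_variance <- function(p, a) {
  if (any(p <= 0 | p >= 1)) stop("allele frequency must be in (0, 1)")
  2 * p * (1 - p) * a^2
}

#' Additive variance of a multi-allelic haplotype locus
#'
#' Double sum over ordered allele pairs `l > i` of
#' `(a_i - a_l)^2 p_i p_l`, which equals the frequency-weighted variance of
#' the allele effects. Note the biallelic inconsistency of the two printed
#' conventions: at `k = 2` this pairwise form equals *half* of
#' [snp_variance()] evaluated at the effect difference `a_1 - a_2`. The
#' default `scale = "as_printed"` keeps the pairwise form;
#' `scale = "snp_consistent"` doubles it so the `k = 2` case coincides with
#' the SNP formula.
#'
#' @param freqs Allele frequencies (sum to 1 within `tol`).
#' @param effects Per-allele substitution effects (kg), same length.
#' @param scale `"as_printed"` (default) or `"snp_consistent"`.
#' @param tol Tolerance on the frequency sum (default 1e-6).
#' @return Additive genetic variance (kg^2).
#' @export
haplotype_variance <- function(freqs, effects,
                               scale = c("as_printed", "snp_consistent"),
                               tol = 1e-6) {
  scale <- match.arg(scale)
  k <- length(freqs)
  stopifnot(length(effects) == k, k >= 1)
  if (abs(sum(freqs) - 1) > tol) {
    stop("allele frequencies sum to ", sum(freqs), ", not 1")
  }
  if (k == 1L) return(0)
  # sum_{i<l} (a_i - a_l)^2 p_i p_l == E_p[a^2] - E_p[a]^2
  mu <- sum(freqs * effects)
  v <- sum(freqs * effects^2) - mu^2
  if (scale == "snp_consistent") v <- 2 * v
  v
}

#' Per-locus additive variances from an association scan
#'
#' Collapses the per-allele rows of [assoc_scan()] output to one variance
#' per locus: the SNP formula for biallelic loci tested at `w = 1` is
#' recovered automatically since the pairwise form with the paired +/-
#' effects reduces to it (up to the documented scale convention, which is
#' applied uniformly).
#'
#' @param assoc Data frame from [assoc_scan()].
#' @param scale Passed to [haplotype_variance()].
#' @param snp_formula If `TRUE` (used for the single-SNP analysis), loci are
#'   biallelic and `sigma^2 = 2 p (1-p) a^2` is applied to the first allele
#'   row instead of the pairwise form.
#' @return Data frame with one row per locus: coordinates, `k`, `sigma2`.
#' @export
locus_variances <- function(assoc, scale = c("as_printed", "snp_consistent"),
                            snp_formula = FALSE) {
  scale <- match.arg(scale)
  sp <- split(seq_len(nrow(assoc)), assoc$window)
  rows <- lapply(sp, function(ii) {
    a <- assoc[ii, , drop = FALSE]
    tested <- !is.na(a$effect)
    if (!any(tested)) {
      s2 <- NA_real_
    } else if (snp_formula) {
      if (nrow(a) != 2L) stop("snp_formula requires biallelic loci")
      j <- which(tested)[1]
      s2 <- snp_variance(a$freq[j], a$effect[j])
    } else {
      # untested (constant-dosage) alleles cannot occur for k >= 2 loci with
      # all alleles present; guard anyway by dropping NA effects and
      # renormalizing
      s2 <- haplotype_variance(a$freq[tested] / sum(a$freq[tested]),
                               a$effect[tested], scale = scale)
    }
    data.frame(chrom = a$chrom[1], window = a$window[1],
               first_id = a$first_id[1], last_id = a$last_id[1],
               start_bp = a$start_bp[1], end_bp = a$end_bp[1],
               k = a$k[1], sigma2 = s2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$window), , drop = FALSE]
  rownames(out) <- NULL
  out
}
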