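# Machine-readable transcriptions of the study's result tables, shipped as
# package fixtures, and consistency checks over them.

#' Load the top single-SNP table fixture
#'
#' Eight SNP markers with per-allele frequencies, substitution effects
#' (+/- pairs), and the printed additive genetic variances.
#'
#' @return Data frame with 8 rows.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_snp_variances.tsv",
                      package = "haploscan", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Load the QTL-region table fixture
#'
#' Thirty-three QTL regions with bp spans, LD class, and the best additive
#' variance per analysis (single-SNP and the five haplotype window sizes);
#' NA means the analysis did not detect the region.
#'
#' @return Data frame with 33 rows.
#' @export
load_table2 <- function() {
  path <- system.file("extdata", "table2_qtl_regions.tsv",
                      package = "haploscan", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Recompute the single-SNP variances of the top-SNP table
#'
#' Applies `sigma^2 = 2 p (1 - p) a^2` to each row's printed minor allele
#' frequency and substitution effect and compares with the printed variance.
#' Printed inputs are rounded to 2-3 decimals, so deviations up to
#' `tol` kg^2 are expected and accepted.
#'
#' @param tab Table fixture (default [load_table1()]).
#' @param tol Maximum accepted absolute deviation in kg^2 (default 0.002).
#' @return Data frame per row: recomputed variance, printed variance,
#'   deviation, pass.
#' @export
verify_table1 <- function(tab = load_table1(), tol = 0.002) {
  need <- c("marker", "freq1", "effect1", "var_kg2")
  if (!all(need %in% names(tab))) stop("malformed table fixture")
  recomputed <- snp_variance(tab$freq1, tab$effect1)
  dev <- abs(recomputed - tab$var_kg2)
  data.frame(
    marker = tab$marker,
    p = tab$freq1, a = abs(tab$effect1),
    recomputed = recomputed,
    printed = tab$var_kg2,
    deviation = dev,
    pass = dev <= tol,
    stringsAsFactors = FALSE
  )
}

#' Detection tallies over the QTL-region table
#'
#' Per-analysis detection counts and truncated percentages, the number of
#' regions detected by all five haplotype window sizes, the number detected
#' by at least two, the maximum haplotype-window variance, and LD-class
#' tallies.
#'
#' @param tab Table fixture (default [load_table2()]).
#' @return List with `summary` (per-analysis counts/percent), `n_all_five`,
#'   `n_at_least_two`, `max_hap_var`, `ld_tally`.
#' @export
verify_table2 <- function(tab = load_table2()) {
  sw_cols <- c("var_sw3", "var_sw5", "var_sw7", "var_sw9", "var_sw11")
  need <- c("bta", "var_snp", sw_cols, "ld")
  if (!all(need %in% names(tab))) stop("malformed table fixture")
  vc <- c("var_snp", sw_cols)
  regions <- tab
  names(regions)[match(vc, names(regions))] <-
    paste0("var_", c("SNP", "SW3", "SW5", "SW7", "SW9", "SW11"))
  summ <- detection_summary(regions)
  det <- !is.na(tab[, sw_cols])
  list(
    summary = summ,
    n_regions = nrow(tab),
    n_all_five = sum(rowSums(det) == 5L),
    n_at_least_two = sum(rowSums(det) >= 2L),
    max_hap_var = max(as.matrix(tab[, sw_cols]), na.rm = TRUE),
    ld_tally = table(tab$ld)
  )
}
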