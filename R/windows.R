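# Overlapping sliding windows of consecutive SNPs and per-window haplotype
# allele enumeration with 0/1/2 diplotype dosage coding.

#' Build sliding windows of w consecutive SNPs
#'
#' Windows advance one SNP at a time (step 1, overlapping) and never span
#' chromosomes, so a chromosome with `n` SNPs yields `max(0, n - w + 1)`
#' windows. `w = 1` degenerates to the single-SNP analysis.
#'
#' @param x A [phased_genotypes()] object, or a variant map data frame with
#'   columns `chrom`, `pos`, `id`.
#' @param w Window size in SNPs (odd sizes 1, 3, 5, 7, 9, 11 are the
#'   supported analyses).
#' @return A `window_set`: list with `w` and a data frame `windows`
#'   (`chrom`, `first`, `last` global variant indices, `start_bp`, `end_bp`,
#'   `first_id`, `last_id`).
#' @export
build_windows <- function(x, w) {
  map <- if (inherits(x, "phased_geno")) x$map else x
  stopifnot(is.data.frame(map), w >= 1, w == as.integer(w))
  if (!(w %in% c(1, 3, 5, 7, 9, 11))) {
    warning("window size ", w, " is outside the standard set {1,3,5,7,9,11}")
  }
  w <- as.integer(w)
  chroms <- unique(map$chrom)
  out <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    idx <- which(map$chrom == chroms[i])
    if (length(idx) > 1L && any(diff(idx) != 1L)) {
      stop("variant map must be grouped by chromosome")
    }
    n <- length(idx)
    if (n < w) {
      warning("chromosome ", chroms[i], " has ", n,
              " SNPs, fewer than window size ", w, "; zero windows")
      next
    }
    first <- idx[seq_len(n - w + 1L)]
    last <- first + w - 1L
    out[[i]] <- data.frame(
      chrom = chroms[i], first = first, last = last,
      start_bp = map$pos[first], end_bp = map$pos[last],
      first_id = map$id[first], last_id = map$id[last],
      stringsAsFactors = FALSE
    )
  }
  windows <- do.call(rbind, out)
  if (is.null(windows)) {
    windows <- data.frame(chrom = character(), first = integer(),
                          last = integer(), start_bp = integer(),
                          end_bp = integer(), first_id = character(),
                          last_id = character(), stringsAsFactors = FALSE)
  }
  structure(list(w = w, windows = windows), class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat("window_set: w =", x$w, ",", nrow(x$windows), "windows on",
      length(unique(x$windows$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Enumerate the haplotype alleles of one window
#'
#' Distinct haplotype strings over the window's SNPs become the alleles of a
#' multi-allelic locus; each sample's diplotype is coded as a 0/1/2 dosage
#' per allele. Alleles are sorted by descending frequency, ties broken
#' lexicographically by allele string.
#'
#' @param geno A [phased_genotypes()] object (complete: missing alleles
#'   inside the window are an error).
#' @param window Either a row index into a `window_set`, or a list/row with
#'   `first` and `last` variant indices.
#' @param window_set The `window_set` the index refers to (when `window` is
#'   an index).
#' @param pool_rare If `TRUE`, alleles observed on fewer than 2 haplotype
#'   copies are pooled into a single `"other"` class (default `FALSE`: all
#'   alleles retained).
#' @return A `hap_locus`: list with `alleles` (character), `freq`, `k`,
#'   `dosage` (n x k integer matrix) and the window coordinates.
#' @export
enumerate_locus <- function(geno, window, window_set = NULL,
                            pool_rare = FALSE) {
  stopifnot(inherits(geno, "phased_geno"))
  if (is.numeric(window) && length(window) == 1L) {
    stopifnot(!is.null(window_set))
    window <- window_set$windows[window, ]
  }
  first <- window$first
  last <- window$last
  cols <- first:last
  h <- geno$hap[, cols, drop = FALSE]
  if (anyNA(h)) {
    bad <- which(rowSums(is.na(h)) > 0)[1]
    stop("missing allele inside window ", window$first_id, "-",
         window$last_id, " for sample ", geno$samples[ceiling(bad / 2)])
  }
  w <- length(cols)
  key <- as.integer(h %*% 2L^(seq_len(w) - 1L))
  tab <- table(key)
  keys <- as.integer(names(tab))
  counts <- as.integer(tab)
  strings <- vapply(keys, function(k) {
    paste(bitwAnd(bitwShiftR(k, seq_len(w) - 1L), 1L), collapse = "")
  }, character(1))
  if (pool_rare && any(counts < 2L) && sum(counts < 2L) > 0L) {
    rare <- counts < 2L
    if (any(!rare)) {
      pooled_count <- sum(counts[rare])
      keys_keep <- keys[!rare]
      strings <- c(strings[!rare], "other")
      counts <- c(counts[!rare], pooled_count)
      key[!(key %in% keys_keep)] <- -1L
      keys <- c(keys_keep, -1L)
    }
  }
  ord <- order(-counts, strings)
  keys <- keys[ord]; counts <- counts[ord]; strings <- strings[ord]
  k <- length(keys)
  n <- length(geno$samples)
  allele_idx <- match(key, keys)
  sample_idx <- rep(seq_len(n), each = 2L)
  dosage <- matrix(0L, n, k)
  inc <- tabulate((allele_idx - 1L) * n + sample_idx, nbins = n * k)
  dosage[] <- inc
  rownames(dosage) <- geno$samples
  colnames(dosage) <- strings
  structure(list(
    chrom = window$chrom, first = first, last = last,
    start_bp = window$start_bp, end_bp = window$end_bp,
    first_id = window$first_id, last_id = window$last_id,
    w = w, alleles = strings, freq = counts / (2 * n), k = k,
    dosage = dosage
  ), class = "hap_locus")
}

#' @export
print.hap_locus <- function(x, ...) {
  cat("hap_locus ", x$first_id, "-", x$last_id, " (", x$chrom, ":",
      x$start_bp, "-", x$end_bp, "): k = ", x$k, " alleles\n", sep = "")
  print(stats::setNames(round(x$freq, 4), x$alleles))
  invisible(x)
}

#' Tabulate the haplotype loci of a window set
#'
#' @param geno A [phased_genotypes()] object.
#' @param ws A `window_set` from [build_windows()].
#' @param pool_rare Passed to [enumerate_locus()].
#' @return Data frame with one row per locus: window coordinates, `k`, and
#'   comma-separated allele strings and frequencies.
#' @export
locus_table <- function(geno, ws, pool_rare = FALSE) {
  rows <- lapply(seq_len(nrow(ws$windows)), function(i) {
    loc <- enumerate_locus(geno, i, ws, pool_rare = pool_rare)
    data.frame(
      chrom = loc$chrom, window = i, first_id = loc$first_id,
      last_id = loc$last_id, start_bp = loc$start_bp, end_bp = loc$end_bp,
      k = loc$k,
      alleles = paste(loc$alleles, collapse = ","),
      freqs = paste(signif(loc$freq, 6), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
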