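# Pairwise r^2 from phased haplotypes, LD decay summaries, merging of
# significant windows into QTL regions, and per-analysis detection tallies.

#' Pairwise r-squared between two markers
#'
#' Computed directly from phased haplotype frequencies:
#' `r^2 = (p_AB - p_A p_B)^2 / (p_A (1-p_A) p_B (1-p_B))`.
#'
#' @param geno A [phased_genotypes()] object.
#' @param i,j Variant indices (or marker ids).
#' @return r^2 in `[0, 1]`.
#' @export
pairwise_r2 <- function(geno, i, j) {
  stopifnot(inherits(geno, "phased_geno"))
  if (is.character(i)) i <- match(i, geno$map$id)
  if (is.character(j)) j <- match(j, geno$map$id)
  a <- geno$hap[, i]
  b <- geno$hap[, j]
  ok <- !is.na(a) & !is.na(b)
  pa <- mean(a[ok]); pb <- mean(b[ok]); pab <- mean(a[ok] * b[ok])
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) {
    stop("monomorphic marker in r^2 computation")
  }
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' LD class from a mean r-squared
#'
#' Strong (`r^2 > 0.6`), moderate (`0.2 < r^2 <= 0.6`), weak
#' (`0.1 < r^2 <= 0.2`), not in LD (`r^2 <= 0.1`). Boundary values are
#' assigned to the weaker class.
#'
#' @param r2 Numeric vector of mean r^2 values (NA allowed).
#' @return Character vector in `{"S", "M", "W", "N"}` (NA propagated).
#' @export
ld_class <- function(r2) {
  out <- rep(NA_character_, length(r2))
  ok <- !is.na(r2)
  out[ok & r2 > 0.6] <- "S"
  out[ok & r2 > 0.2 & r2 <= 0.6] <- "M"
  out[ok & r2 > 0.1 & r2 <= 0.2] <- "W"
  out[ok & r2 <= 0.1] <- "N"
  out
}

#' LD decay curve by distance bin
#'
#' All intra-chromosomal marker pairs within `max_dist` are binned by
#' distance; the mean r^2 per bin is reported. For large panels the pairs of
#' each chromosome can be subsampled (`max_pairs`, seeded).
#'
#' @param geno A [phased_genotypes()] object (>= 2 markers per chromosome).
#' @param max_dist Maximum pair distance in bp (default 1e6).
#' @param bin_width Bin width in bp (default 5e4).
#' @param max_pairs Optional cap on pairs per chromosome (subsampled).
#' @param seed Seed used when subsampling (logged via message).
#' @return Data frame `bin_start`, `bin_end`, `mean_r2` (NA for empty bins),
#'   `n_pairs`.
#' @export
decay_curve <- function(geno, max_dist = 1e6, bin_width = 5e4,
                        max_pairs = NULL, seed = 1L) {
  stopifnot(inherits(geno, "phased_geno"))
  nb <- ceiling(max_dist / bin_width)
  sums <- numeric(nb)
  counts <- integer(nb)
  for (ch in unique(geno$map$chrom)) {
    idx <- which(geno$map$chrom == ch)
    if (length(idx) < 2L) stop("need >= 2 markers per chromosome (", ch, ")")
    pos <- geno$map$pos[idx]
    h <- geno$hap[, idx, drop = FALSE]
    r2 <- suppressWarnings(stats::cor(h))^2
    pr <- which(upper.tri(r2), arr.ind = TRUE)
    d <- pos[pr[, 2]] - pos[pr[, 1]]
    keep <- d <= max_dist & is.finite(r2[pr])
    pr <- pr[keep, , drop = FALSE]
    d <- d[keep]
    if (!is.null(max_pairs) && nrow(pr) > max_pairs) {
      set.seed(seed)
      message("subsampling ", max_pairs, " of ", nrow(pr),
              " pairs on chromosome ", ch, " (seed ", seed, ")")
      s <- sample.int(nrow(pr), max_pairs)
      pr <- pr[s, , drop = FALSE]
      d <- d[s]
    }
    b <- pmin(pmax(ceiling(d / bin_width), 1L), nb)
    v <- r2[pr]
    sums <- sums + vapply(seq_len(nb), function(x) sum(v[b == x]), numeric(1))
    counts <- counts + vapply(seq_len(nb), function(x) sum(b == x), integer(1))
  }
  data.frame(
    bin_start = (seq_len(nb) - 1L) * bin_width,
    bin_end = seq_len(nb) * bin_width,
    mean_r2 = ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_),
    n_pairs = counts
  )
}

#' Mean pairwise r-squared among the markers of a bp interval
#' @param geno A [phased_genotypes()] object.
#' @param chrom,start,end Interval (1-based inclusive).
#' @return Mean r^2 over all marker pairs in the interval (NA if < 2
#'   polymorphic markers).
#' @export
region_mean_r2 <- function(geno, chrom, start, end) {
  idx <- which(geno$map$chrom == chrom & geno$map$pos >= start &
                 geno$map$pos <= end)
  if (length(idx) < 2L) return(NA_real_)
  r2 <- suppressWarnings(stats::cor(geno$hap[, idx, drop = FALSE]))^2
  mean(r2[upper.tri(r2)], na.rm = TRUE)
}

#' Merge significant windows into QTL regions
#'
#' Flagged haplotype windows whose bp spans overlap or abut on the same
#' chromosome are merged transitively into regions; flagged single SNPs join
#' a region they fall inside, otherwise they form singleton regions. Per
#' analysis the best (maximum) member variance is recorded.
#'
#' @param flagged Data frame of flagged loci with columns `chrom`,
#'   `start_bp`, `end_bp`, `first_id`, `last_id`, `sigma2`, `analysis`
#'   (e.g. `"SNP"`, `"SW3"`, ...). Single-SNP rows have
#'   `start_bp == end_bp`.
#' @param geno Optional panel for the per-region mean r^2 / LD class.
#' @return Data frame of regions: `chrom`, `start_bp`, `end_bp`, `first_id`,
#'   `last_id`, `span_bp`, one `var_<analysis>` column per analysis, and
#'   `mean_r2` / `ld` when `geno` is given. Empty input gives zero rows.
#' @export
merge_regions <- function(flagged, geno = NULL) {
  analyses <- unique(flagged$analysis)
  empty <- data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), first_id = character(),
                      last_id = character(), span_bp = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(flagged) == 0L) return(empty)
  is_snp <- flagged$analysis == "SNP"
  win <- flagged[!is_snp, , drop = FALSE]
  snp <- flagged[is_snp, , drop = FALSE]

  regions <- list()
  for (ch in unique(win$chrom)) {
    wc <- win[win$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(start = wc$start_bp, end = wc$end_bp)
    red <- IRanges::reduce(ir, min.gapwidth = 1L)
    hits <- IRanges::findOverlaps(ir, red)
    for (r in seq_along(red)) {
      memb <- wc[S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == r], ,
                 drop = FALSE]
      first <- memb$first_id[which.min(memb$start_bp)]
      last <- memb$last_id[which.max(memb$end_bp)]
      regions[[length(regions) + 1L]] <- list(
        chrom = ch, start_bp = min(memb$start_bp), end_bp = max(memb$end_bp),
        first_id = first, last_id = last, members = memb
      )
    }
  }
  # single-SNP flags: attach to an enclosing region, else a singleton region
  if (nrow(snp) > 0L) {
    for (i in seq_len(nrow(snp))) {
      pos <- snp$start_bp[i]
      inside <- which(vapply(regions, function(r) {
        r$chrom == snp$chrom[i] && pos >= r$start_bp && pos <= r$end_bp
      }, logical(1)))
      if (length(inside) > 0L) {
        r <- inside[1]
        regions[[r]]$members <- rbind(regions[[r]]$members, snp[i, ])
      } else {
        regions[[length(regions) + 1L]] <- list(
          chrom = snp$chrom[i], start_bp = pos, end_bp = pos,
          first_id = snp$first_id[i], last_id = snp$last_id[i],
          members = snp[i, , drop = FALSE]
        )
      }
    }
  }
  rows <- lapply(regions, function(r) {
    d <- data.frame(chrom = r$chrom, start_bp = r$start_bp,
                    end_bp = r$end_bp, first_id = r$first_id,
                    last_id = r$last_id, span_bp = r$end_bp - r$start_bp,
                    stringsAsFactors = FALSE)
    for (an in analyses) {
      v <- r$members$sigma2[r$members$analysis == an]
      d[[paste0("var_", an)]] <- if (length(v)) max(v) else NA_real_
    }
    d
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(geno)) {
    out$mean_r2 <- mapply(function(ch, s, e) region_mean_r2(geno, ch, s, e),
                          out$chrom, out$start_bp, out$end_bp)
    out$ld <- ld_class(out$mean_r2)
  }
  out
}

#' Per-analysis detection counts over QTL regions
#'
#' A region counts as detected by an analysis when it contains at least one
#' window (or SNP) flagged by that analysis. Percentages are integer percent
#' of the total region count, truncated toward zero.
#'
#' @param regions Data frame from [merge_regions()] (or any data frame with
#'   `var_<analysis>` columns where non-NA means detected).
#' @return Data frame `analysis`, `n_detected`, `pct`.
#' @export
detection_summary <- function(regions) {
  if (nrow(regions) == 0L) stop("no regions to summarize")
  vc <- grep("^var_", names(regions), value = TRUE)
  if (length(vc) == 0L) stop("no per-analysis variance columns found")
  data.frame(
    analysis = sub("^var_", "", vc),
    n_detected = vapply(vc, function(cl) sum(!is.na(regions[[cl]])), integer(1)),
    pct = vapply(vc, function(cl) {
      as.integer(floor(100 * sum(!is.na(regions[[cl]])) / nrow(regions)))
    }, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write regions as a BED-like file
#'
#' BED conformance: 0-based half-open intervals, columns chrom, start, end,
#' name, score (best variance across analyses), LD class.
#'
#' @param regions Data frame from [merge_regions()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  vc <- grep("^var_", names(regions), value = TRUE)
  best <- apply(regions[, vc, drop = FALSE], 1, max, na.rm = TRUE)
  bed <- data.frame(
    chrom = regions$chrom,
    start = regions$start_bp - 1L,
    end = regions$end_bp,
    name = paste0(regions$first_id, "-", regions$last_id),
    score = signif(best, 4),
    ld = if ("ld" %in% names(regions)) regions$ld else "."
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
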