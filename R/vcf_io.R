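# Reading and writing phased VCF panels. Parsing is delegated to vcfR; this
# layer enforces the contract the downstream analysis needs: biallelic SNPs
# only, every genotype phased.

#' Read a phased VCF into a genotype panel
#'
#' Only biallelic SNP records are accepted and every genotype must be phased
#' (`|` separator) or fully missing; an unphased genotype is an error naming
#' the offending sample and position.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return A [phased_genotypes()] object.
#' @export
read_phased_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    stop("multi-allelic records are not supported (only biallelic SNPs): ",
         paste(head(fix[multi, "ID"]), collapse = ", "))
  }
  non_snp <- nchar(ref) != 1L | nchar(alt) != 1L |
    !(ref %in% c("A", "C", "G", "T")) | !(alt %in% c("A", "C", "G", "T"))
  if (any(non_snp)) {
    stop("non-SNP alleles are not supported: ",
         paste(head(fix[non_snp, "ID"]), collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  m <- nrow(gt)
  n <- length(samples)
  miss <- is.na(gt) | gt %in% c(".", "./.", ".|.")
  unphased <- !miss & !grepl("|", gt, fixed = TRUE)
  if (any(unphased)) {
    idx <- which(unphased, arr.ind = TRUE)
    msgs <- apply(utils::head(idx, 5), 1, function(r) {
      paste0(samples[r[2]], " at ", fix[r[1], "CHROM"], ":", fix[r[1], "POS"])
    })
    stop("unphased genotype(s) found: ", paste(msgs, collapse = "; "))
  }
  a1 <- matrix(NA_integer_, m, n)
  a2 <- matrix(NA_integer_, m, n)
  ok <- !miss
  parts <- strsplit(gt[ok], "|", fixed = TRUE)
  bad_len <- lengths(parts) != 2L
  if (any(bad_len)) stop("malformed GT field(s), expected two alleles")
  al <- matrix(suppressWarnings(as.integer(unlist(parts))), nrow = 2L)
  if (any(is.na(al)) || any(al > 1L)) {
    stop("GT alleles must be 0, 1 or missing")
  }
  a1[ok] <- al[1L, ]
  a2[ok] <- al[2L, ]
  # interleave: rows 2i-1, 2i are the two haplotypes of sample i
  hap <- matrix(NA_integer_, 2L * n, m)
  hap[seq(1L, 2L * n, 2L), ] <- t(a1)
  hap[seq(2L, 2L * n, 2L), ] <- t(a2)
  map <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"]),
    ref = ref, alt = alt, stringsAsFactors = FALSE
  )
  phased_genotypes(samples = samples, map = map, hap = hap)
}

#' Write a genotype panel as a phased VCF
#'
#' @param geno A [phased_genotypes()] object.
#' @param path Output path (plain text).
#' @return The path, invisibly.
#' @export
write_phased_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "phased_geno"))
  n <- length(geno$samples)
  odd <- geno$hap[seq(1L, 2L * n, 2L), , drop = FALSE]
  even <- geno$hap[seq(2L, 2L * n, 2L), , drop = FALSE]
  gt <- matrix(paste0(ifelse(is.na(odd), ".", odd), "|",
                      ifelse(is.na(even), ".", even)), n, nrow(geno$map))
  gt[is.na(odd) & is.na(even)] <- ".|."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=haploscan",
    paste0("##contig=<ID=", unique(geno$map$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples), collapse = "\t")
  )
  body <- paste(geno$map$chrom, geno$map$pos, geno$map$id, geno$map$ref,
                geno$map$alt, ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
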