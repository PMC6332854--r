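# Shared fixture builders. All fixtures are constructed in code; nothing is
# read from disk except the packaged table transcriptions.

# Hand-built phased panel from a matrix of haplotype rows (2 per sample).
toy_geno <- function(hap, pos = NULL, chrom = "1") {
  hap <- as.matrix(hap)
  storage.mode(hap) <- "integer"
  n <- nrow(hap) / 2
  m <- ncol(hap)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  phased_genotypes(
    samples = sprintf("s%02d", seq_len(n)),
    map = data.frame(chrom = rep(chrom, m), pos = as.integer(pos),
                     id = paste0("m", seq_len(m)),
                     ref = rep("A", m), alt = rep("G", m),
                     stringsAsFactors = FALSE),
    hap = hap
  )
}

# Small simulated panel reused by several window/model tests.
small_panel <- function(seed = 11, n = 120, snps = 200) {
  cfg <- sim_config(n_individuals = n, n_chromosomes = 1, snps_per_chrom = snps,
                    chrom_length_bp = 2e6, n_contemporary_groups = 8,
                    seed = seed)
  generate_haplotypes(cfg)
}

# Independent brute-force oracle for the pairwise haplotype variance:
# sum over ordered pairs l > i of (a_i - a_l)^2 p_i p_l.
brute_hap_variance <- function(freqs, effects) {
  k <- length(freqs)
  tot <- 0
  if (k < 2) return(0)
  for (i in seq_len(k - 1)) {
    for (l in (i + 1):k) {
      tot <- tot + (effects[i] - effects[l])^2 * freqs[i] * freqs[l]
    }
  }
  tot
}

# Dirichlet-ish random frequency vector.
rand_freqs <- function(k) {
  x <- stats::rexp(k)
  x / sum(x)
}
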