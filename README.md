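# haploscan

Sliding-window haplotype genome-wide association analysis (GWAA) for
quantitative traits, built for the setting where it matters most: livestock
populations with short-range linkage disequilibrium (LD), a dense phased SNP
panel, and causal variants that no single typed SNP tags well. The
motivating trait is Warner-Bratzler shear force (WBSF, kg), a mechanical
measure of beef tenderness.

Single-SNP GWAA tests each marker alone. `haploscan` additionally treats
every run of `w` consecutive SNPs (`w` = 3, 5, 7, 9, 11; overlapping
windows, step one SNP) as one multi-allelic locus whose alleles are the
observed haplotype strings, coded per animal as 0/1/2 copies. Each allele
is tested one-vs-rest in the linear mixed model

    y = 1mu + x beta + u + e,   u ~ N(0, G Vg),   e ~ N(0, I Ve)

with `G` the genomic relationship matrix from standardized genotypes
(`G = WW'/m`), the trait pre-adjusted for contemporary group and age at
slaughter, and the null-model variance ratio reused per predictor
(EMMAX-style; exact per-predictor REML is available). Per-allele effects
`a_i` and frequencies `p_i` become the locus's additive genetic variance:

    SNP:        sigma^2 = 2 p (1 - p) a^2
    haplotype:  sigma^2 = sum_{i<l} (a_i - a_l)^2 p_i p_l   (= Var_p(a))

Genome-wide, each analysis's variances are fitted with a gamma distribution
(method-of-moments shape/rate, per allele-count class for haplotypes, with
cubic/Brody smoothing of the parameters over allele counts); a locus is
significant when its variance reaches the gamma quantile at probability
`1 - 0.05/N` (Bonferroni over the `N` loci of that scan). Significant
windows merge into QTL regions with LD classes (S/M/W/N by mean pairwise
r²). A founder-copying simulator generates phased panels with realistic LD
decay and phenotypes with contemporary-group, age, polygenic and planted-QTL
structure, so the entire pipeline is testable offline.

## Worked example

Simulate a 500-animal study (two 10 Mb chromosomes, ~2,000 phased SNPs)
with one *untyped* QTL at chr1:5,000,000 — its causal site is withheld from
the panel, so only flanking-SNP haplotypes can tag it — then run the
single-SNP, SW3 and SW5 analyses:

```r
library(haploscan)

q   <- qtl_spec("1", 5e6, "untyped_tagged", effect = 0.54, causal_freq_target = 0.2)
cfg <- sim_config(n_individuals = 500, n_chromosomes = 2, snps_per_chrom = 1000,
                  chrom_length_bp = 1e7, qtls = list(q), seed = 506)
st  <- simulate_study(cfg)
st$truth$qtl
#>   chrom     pos           mode effect target_freq realized_freq realized_var
#> 1     1 5000000 untyped_tagged   0.54         0.2         0.166   0.07999307

res <- run_pipeline(run_config(window_sizes = c(1, 3, 5), seed = 506),
                    geno = st$geno, pheno = st$pheno)
#> QC: 500 samples, 2000 markers retained
#> null model: Vg = 0.54, Ve = 2.814
#> SNP: 2000 loci tested, 0 flagged
#> SW3: 1996 loci tested, 0 flagged
#> SW5: 1992 loci tested, 1 flagged
#> regions: 1 (seed 506)

res$regions
#>   chrom start_bp  end_bp      first_id       last_id span_bp   var_SW5  mean_r2 ld
#> 1     1  4978251 5032116 snp_1_4978251 snp_1_5032116   53865 0.1671576 0.135089  W
```

The planted QTL contributes 0.080 kg^2 of additive variance through a causal
site the panel does not contain. The single-SNP scan finds nothing — no
typed SNP is in strong enough LD with the withheld causal variant — while
the 5-SNP haplotype scan flags one window whose 54 kb span covers the causal
position exactly, explaining 0.167 kg^2 at the locus level in a weak-LD
region (mean pairwise r^2 = 0.14). That contrast — haplotype windows
recovering QTL that single SNPs miss — is the package's reason to exist.
(At this desk scale the Bonferroni-corrected gamma threshold is demanding;
across seeded replicates the haplotype scans detect such a QTL in a minority
of runs and the single-SNP scan less often still — the methods vignette
quantifies this.)

The packaged transcriptions of the published result tables can be checked
any time:

```r
head(verify_table1(), 3)
#>        marker     p    a recomputed printed
#> 1 rs109294639 0.094 0.40 0.02725248   0.027
#> 2 rs134499129 0.163 0.51 0.07097141   0.072
#> 3  rs41595711 0.185 0.30 0.02713950   0.027
```

A thin command-line wrapper (`inst/cli/haploscan.R`) exposes `simulate`,
`run` and `verify-tables` subcommands over the same functions, with
YAML-file configuration (`read_run_config()`).

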