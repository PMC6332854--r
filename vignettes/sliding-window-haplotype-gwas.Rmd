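---
title: "Sliding-window haplotype GWAS: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window haplotype GWAS: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`haploscan` implements a haplotype-based genome-wide association workflow for
a quantitative trait — the motivating application is Warner-Bratzler shear
force (WBSF, kg), a mechanical measure of beef tenderness, in an indicine
cattle population. Single-SNP association tests can miss causal variants
that are poorly tagged by any one typed SNP, particularly in populations
with short-range linkage disequilibrium (LD). Haplotypes of `w` consecutive
SNPs, advanced one SNP at a time ("sliding windows"), act as multi-allelic
markers that can be in much stronger LD with an untyped causal variant than
any of their constituent SNPs. The package runs the single-SNP analysis
(`w = 1`) and window sizes 3, 5, 7, 9 and 11 under one engine and compares
what each detects.

# The model

## Haplotype loci and dosage coding

On each chromosome with SNPs $(\mathrm{SNP}_1, \dots, \mathrm{SNP}_n)$ the
windows are $(1..w), (2..w{+}1), \dots, (n{-}w{+}1..n)$ — overlapping, step
one, never spanning chromosomes, so a chromosome contributes
$\max(0, n - w + 1)$ loci. The distinct haplotype strings observed in the
phased sample are the alleles of locus $j$; $k_j$ denotes their number and
$p_{ij}$ their frequencies. Each animal's diplotype is coded per allele as
0, 1 or 2 copies, so a locus yields $k_j$ dosage vectors that sum to the
constant 2 across alleles (which is why the $k_j$ allele effects are only
estimable one-vs-rest, not jointly with an intercept).

Alleles are defined by exact string identity; no similarity clustering and
no frequency floor are applied by default. A `pool_rare` switch (off by
default) folds alleles observed on fewer than two haplotype copies into an
`"other"` class for sensitivity analysis.

## Mixed-model association

The trait is first pre-adjusted for contemporary group (CG, a herd/year/
management cohort, fixed classes) and age at slaughter (linear covariate,
days), with the fixed effects estimated by REML under an animal model whose
random effect has covariance proportional to the genomic relationship
matrix (GRM). Each predictor dosage $x$ is then tested in

$$y = 1\mu + x\beta + u + e,\qquad
  u \sim \mathcal{N}(0,\, G\,V_g),\quad e \sim \mathcal{N}(0,\, I\,V_e),$$

where $G$ is the GRM from standardized genotypes: column $j$ centred by
$2p_j$ and scaled by $1/\sqrt{2p_j(1-p_j)}$, $G = WW^\top/m$. The same GRM
serves every window size and the single-SNP scan, and markers inside the
tested window are not excluded from it (no leave-one-chromosome-out; a
`LOCO`-style analysis can be emulated by passing a GRM built from a marker
subset, but the default mirrors the single-GRM procedure). One
eigendecomposition of $G$ rotates the model to independent errors; the null
variance ratio $\lambda = V_g/V_e$ is found by 1-D REML optimization and
re-used for every predictor (the EMMAX/"population parameters previously
determined" device). `exact = TRUE` re-optimizes $\lambda$ per predictor;
on desk-scale panels the two agree closely, which the test suite checks.

Multi-allelic loci are fitted as $k_j$ separate one-vs-rest regressions, so
every allele — including the last — receives its own substitution effect
$a_{ij}$ and Wald p-value. For a biallelic SNP this yields the familiar
paired $\pm a$ effects with a shared p-value. A joint $(k-1)$-column fit is
deliberately not the default: the variance formula below consumes an effect
per allele.

## Additive genetic variance

For a SNP with allele frequency $p$ and substitution effect $a$:
$\sigma^2 = 2p(1-p)a^2$. For a haplotype locus:

$$\sigma_j^2 \;=\; \sum_{i<l} (a_{ij} - a_{lj})^2\, p_{ij}\, p_{lj},$$

which equals the frequency-weighted variance $\mathrm{Var}_p(a)$ of the
allele effects. The two formulas disagree by a factor of two at $k = 2$:
the pairwise form equals $\tfrac12 \cdot 2p(1-p)(a_1-a_2)^2$. Both
conventions are printed in the source literature of this method family;
`variance_scale = "as_printed"` (default) keeps the pairwise form for
haplotype loci and the $2p(1-p)a^2$ form for SNPs, while
`"snp_consistent"` doubles the pairwise form so the biallelic case
coincides. Because thresholds are fitted within each analysis, flagging is
internally consistent under either convention.

## Gamma significance thresholds

Genome-wide, the per-locus variances of an analysis are modelled as
Gamma($\alpha$, rate $\beta$). The parameters come from the
Newton–Raphson-derived moment approximation: with
$s = \ln \bar{\sigma^2} - \overline{\ln \sigma^2}$,

$$\hat\alpha = \frac{3 - s + \sqrt{(3-s)^2 + 24 s}}{12 s},
  \qquad \hat\beta = \hat\alpha / \bar{\sigma^2}.$$

A locus is significant when its variance reaches the gamma quantile at
probability $1 - 0.05/N$, $N$ the number of loci tested in that analysis
(Bonferroni over the genome-wide scan; the family level 0.05 is
configurable). Zero variances are excluded from fitting (gamma support is
positive) with a logged count.

Haplotype-locus variances grow with the allele count $k$ — each extra
allele contributes estimation noise of order $V_e/2n$ — so the gamma
parameters are fitted per $k$ class and then smoothed over $k$: a cubic
polynomial for $\hat\alpha(k)$ and the Brody asymptotic curve
$\hat\beta(k) = A(1 - Be^{-\kappa k})$ for the rate, fitted by nonlinear
least squares (starting values $A = \max\hat\beta$,
$B = 1 - \hat\beta(k_{\min})/A$, $\kappa = 0.1$, with perturbed restarts).
The SNP analysis uses its single direct moment fit; smoothing applies only
across haplotype allele-count classes.

Numerical choices here that were genuinely open:

* **Class weighting.** The smoothing regressions weight each class by its
  locus count. Unweighted fits let 2–4-locus edge classes drag the cubic,
  which inflated the family-wise false-flag rate in null calibration runs
  roughly eightfold; with weights the observed rate is statistically
  consistent with the nominal 0.05 (checked against a one-sided binomial
  acceptance bound in the test suite). This is the package's own choice.
* **Extrapolation.** Outside the fitted class range the cubic is not
  trusted; boundary-class parameters are reused there. When fewer than five
  classes are available the class fits are used directly, and classes too
  small to fit borrow the nearest fitted class (logged).
* **Bonferroni count.** $N$ is the total number of loci in the analysis,
  not the class size; per-$k$ parameters with the genome-wide $N$. The
  alternative (per-class $N$) would loosen every threshold and is not
  offered.

## LD summaries and QTL regions

$r^2$ is computed directly from phased haplotype frequencies,
$(p_{AB} - p_A p_B)^2 / p_A(1-p_A)p_B(1-p_B)$ — with phase known there is
no need for an EM genotype estimator. Decay curves bin all
intra-chromosomal pairs by distance. Significant windows of any size whose
bp spans overlap or abut on a chromosome merge transitively into QTL
regions; significant single SNPs join a region they fall inside and
otherwise stand alone. Regions carry the best per-analysis variance, their
mean pairwise $r^2$ and an LD class: strong ($r^2 > 0.6$), moderate
($0.2 < r^2 \le 0.6$), weak ($0.1 < r^2 \le 0.2$), not in LD
($r^2 \le 0.1$) — the published class intervals are open at both ends,
leaving the boundary values unassigned, so boundaries go to the weaker
class here. Detection percentages over regions are reported as integer
percent truncated toward zero (floor), the convention consistent with the
published 57% for 19 of 33 regions.

# The synthetic-data generator

No genotypes were deposited with the study, so the package ships a
simulator whose defaults emulate the study conditions and make every stage
testable offline:

* **Haplotypes.** Each of the $2n$ sample haplotypes copies segments from
  50 founder templates, switching template with per-bp probability
  `switch_rate` (geometric segment lengths). The founders themselves are
  mosaics of a small internal ancestral pool (six templates, plus 1%
  site-level noise); independent founder alleles would cap short-range
  $r^2$ near $1/K \approx 0.02$, far below what dense cattle panels show.
  `switch_rate` was calibrated once against the target decay regime and
  frozen at `2e-6`: the default panel shows mean $r^2 \approx 0.18$ below
  20 kb, below 0.15 (measured: < 0.09) beyond 100 kb, declining
  monotonically to ~0.015 at 600 kb.
* **Phenotypes.** $y = 5.9 + \mathrm{CG} + 0.002\,(\mathrm{age} - 691) +
  \sum \mathrm{QTL} + g + e$ with 20 contemporary groups of SD 0.5 kg, ages
  $\mathcal{N}(691, 102^2)$ days truncated at 3 SD, a polygenic vector $g$
  drawn through the Cholesky factor of the realized GRM (jitter $10^{-6}$)
  scaled to `h2_polygenic` (default 0.25) of the trait variance, and the
  residual scaled so the within-group trait variance lands at
  $1.80^2\ \mathrm{kg}^2$. Trait mean/SD, CG count, age distribution and
  heritability mirror the study population's summary statistics; the CG
  effect SD is a realistic choice the study does not report.
* **QTLs.** Causal sites segregate on the same ancestral genealogy as the
  typed variants — the number of carrier ancestors approximates
  `causal_freq_target` — which is what lets flanking haplotypes tag them
  (multi-allelic window $R^2$ with the causal dosage is 0.8–0.99 on the
  default panel, versus single-SNP $r^2$ that varies from ~0.9 down to
  ~0.05 depending on whether a typed SNP happens to share the causal
  ancestral split). `typed_snp` mode emits the causal site as an ordinary
  SNP; `untyped_tagged` withholds it from the emitted map, so only
  flanking-SNP haplotypes can tag it — the mechanism by which sliding
  windows are expected to beat single SNPs. Study-scale simulations plant
  QTLs with variances inside the published 0.03–0.10 kg$^2$ range; the
  power fixture uses a single untyped QTL of ~0.08 kg$^2$ (substitution
  effect 0.54 kg at realized causal frequency ~1/6).

What the generator does **not** emulate: pedigree/family structure beyond
founder sharing, selection, multi-generation recombination maps, genotyping
or imputation error, and allele-frequency spectra shaped by demography.
Passing tests therefore demonstrate the pipeline's statistical behaviour
under a controlled LD structure, not performance on real cattle data.

# Problem sizes and what the tests show

The packaged simulations run at desk scale by design: the standard fixture
is 500 individuals and ~2,000 SNPs over two 10 Mb chromosomes, and the
calibration/power studies use 20 seeded replicates of that fixture. At this
scale the Bonferroni-corrected gamma threshold corresponds to a
non-centrality requirement that a 0.08 kg$^2$ QTL (the top of the published
per-window range) meets only part of the time: measured power for the SW3/
SW5 scans on the untyped-QTL fixture is roughly 15% per seed, and lower
still for the single-SNP scan, which succeeds only when a typed SNP happens
to share the causal variant's ancestral split — the qualitative contrast
the method exists to demonstrate. In the source study's population
(n = 3161, 413,355 SNPs) the same captured variance corresponds to a
four-to-six-fold larger non-centrality, comfortably past the threshold,
which is why the published scans detect such QTL reliably. The test suite
asserts the contrast (haplotype detections strictly exceed single-SNP
detections) and the family-wise false-flag calibration ($\le 0.05$ on null
panels), not an absolute power figure.

# Degenerate inputs and edge behaviour

* `w = 1` reduces the haplotype engine exactly to 0/1/2 genotype coding;
  the suite asserts matrix equality with the GRM input.
* Monomorphic windows give $k = 1$, variance 0, and are excluded from gamma
  fitting; constant dosage columns are skipped with a log line.
* An identity-like GRM leaves $V_g$ and $V_e$ separately unidentifiable;
  the fit warns and returns a boundary estimate.
* One contemporary group with constant age degrades pre-adjustment to mean
  subtraction; groups with fewer than three records are an error, as is a
  CG design collinear with age.
* Unphased genotypes, multi-allelic records and non-SNP alleles are
  rejected at VCF read time, naming the offending sample/record.
* QC boundaries are kept (MAF exactly 0.05 is retained; the filters remove
  strictly-below), samples are filtered before markers, and marker
  frequencies are recomputed after sample removal — the order is asserted
  by a fixture in which a failing sample flips a marker across the MAF
  boundary.
* The Hardy–Weinberg filter is a 1-df chi-square on genotype counts; the
  exact test is deferred (the study does not name its test, and the choice
  only moves a handful of boundary markers).

# Known limitations

* Effects are additive only; no dominance or epistasis within windows,
  although haplotype alleles partially absorb local interactions.
* The per-allele one-vs-rest fits ignore the correlation among a locus's
  allele effects; the variance formula treats the $\hat a_{ij}$ as plain
  numbers, faithfully to the printed method, so estimation noise inflates
  $\sigma_j^2$ with $k$ — handled empirically by the per-$k$ gamma classes
  rather than analytically.
* Gamma tails are an approximation to the true null distribution of
  $\sigma^2$; calibration was verified by simulation at the shipped
  problem sizes, not proved.
* Region spans merge window unions; the alternative reading (best single
  window) is narrower and not offered.
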