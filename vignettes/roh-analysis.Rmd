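---
title: "ROH detection, genomic inbreeding and ROH islands: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROH detection, genomic inbreeding and ROH islands: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
```

## The problem

Runs of homozygosity (ROH) are contiguous stretches of homozygous genotypes
in a diploid genome. They arise when both chromosome copies descend from a
recent common ancestor (autozygosity), so their number, length spectrum and
genomic placement carry information about inbreeding, demography and
selection. In livestock cohorts genotyped on SNP arrays — the motivating
setting here is ten pig breeds, five indigenous and five commercial, on 18
autosomes — three quantities are routinely derived:

* **F_ROH**, the fraction of the SNP-covered autosomal genome inside an
  individual's ROH: `F_ROH = sum_i L_ROHi / L_auto`, with `L_auto` the
  summed first-to-last-SNP span of every autosome on the post-QC map.
* **F_HOM**, the excess-homozygosity inbreeding coefficient
  `(O - E) / (L - E)`, with `O` observed homozygotes, `L` non-missing
  autosomal genotypes, and `E` the homozygote count expected under random
  mating at the cohort allele frequencies.
* **ROH islands**: genomic regions where the fraction of a breed's
  individuals whose ROH cover a SNP reaches a hotspot threshold (40% here),
  pointing at shared selection or drift.

## The ROH scanner

Detection follows the PLINK `--homozyg` sliding-window scheme under seven
criteria (defaults in `roh_params()`):

1. minimum run length 1 Mb;
2. minimum 50 SNPs per run — cross-checked against the Lencz rule
   `l = ln(alpha / (n_s n_i)) / ln(1 - het)` (`min_roh_snps()`), which gives
   `l = 50` at `alpha = 0.05`, 54,075 SNPs, 320 individuals and `het = 0.33`;
   the pipeline logs the computed `l` and uses the configured `min_snps`;
3. maximum 1 Mb gap between consecutive run SNPs;
4. minimum density of 1 SNP per 100 kb;
5. window size 50 SNPs, slid one SNP at a time;
6. at most 1 heterozygous and 5 missing calls per passing window;
7. a SNP qualifies when at least 1% (`window_threshold = 0.01`) of the
   windows containing it pass.

Design points the criteria leave open, and how they are resolved here:

* The per-SNP ratio divides by the number of windows that *actually contain*
  the SNP: chromosome-edge SNPs sit in fewer than 50 windows and would be
  systematically under-called with a fixed denominator.
* Qualifying runs are split at over-gap map intervals *before* the
  SNP-count, length and density tests.
* Runs are trimmed so both terminal SNPs are homozygous non-missing calls: a
  heterozygous or missing call tolerated by the window filter may survive
  inside a run but cannot bound a homozygous segment. No segment-level
  heterozygote cap is applied beyond that.
* Coordinates are 1-based inclusive; `length_bp = end - start + 1`;
  density is `(length_bp/1000) / n_snps` kb per SNP.
* Length classes are half-open `[1,5), [5,10), [10,20), [20,40)` Mb with an
  open final class `[40, Inf)`; each segment is binned whole (no proration).
* The scanner is invariant to allele polarity (0/2 recoding) and its output
  is byte-deterministic given the input.

### Boundary behaviour

The window-threshold rule has a structural consequence worth stating
precisely, because the validation suite deliberately exposes it. Consider a
SNP at distance *d* beyond the end of a long clean homozygous tract. Among
the windows containing it is one holding the last `50 - d` tract SNPs and
the first *d* flanking SNPs; that window passes whenever the flank holds at
most one heterozygote. One passing window out of at most fifty is already
2% ≥ 1%, so the qualifying run extends past the true tract end until the
*second* flanking heterozygote. At a within-breed heterozygosity of
0.35–0.40 that is on the order of 2/het − 1 ≈ 3–5 SNPs (120–200 kb at 40 kb
spacing) per side, before terminal trimming pulls the bound back to the last
homozygous call. The same overrun is documented for PLINK's scanner in the
ROH methods literature and is the reason several authors recommend raising
the window threshold.

Three acceptance expectations are impossible under this rule and are left
red rather than weakened, with the scanner kept faithful to its stated
criteria: mean boundary error within 1 SNP of planted tract bounds
(measured ≈ 3.4 SNPs), `|mean F_ROH − mean planted fraction| ≤ 0.01`
(measured ≈ +0.011, exactly the overrun integrated over ~9 tracts per
individual), and exact SNP-set equality of a called island with its planted
block (the call is a superset by a few flanking SNPs, because carrier-tract
overruns keep flank incidence above the threshold). Everything else about
recovery is met comfortably: sensitivity ≈ 0.98 for planted tracts of at
least 1 Mb and 50 SNPs, precision ≈ 0.98, and correlation ≥ 0.999 between
F_ROH and the planted autozygous fraction.

## Quality control

`apply_qc()` performs one ordered pass, mirroring common PLINK practice of
sample filters before variant filters: (1) drop samples with missing-call
fraction > 0.10; (2) drop variants with missing fraction > 0.05; (3) drop
variants with Hardy–Weinberg exact p < 1e-6; (4) drop variants with
MAF < 0.05. Frequencies and the HWE test use post-stage-1 samples and
non-missing calls only; a monomorphic variant has exact p = 1 and falls at
the MAF stage, never at HWE. The HWE test is the standard two-sided
conditional exact test (probabilities of heterozygote counts no more likely
than observed, given the allele counts), computed with the usual stable
recurrence and no mid-p correction; the suite checks it against direct
log-factorial enumeration for every genotype table with up to 200
individuals at 1e-12.

`expected_homozygotes()` applies the PLINK-style small-sample factor
`n/(n-1)` to `2p(1-p)`; `correction = FALSE` disables it. `L_auto` is
computed on the post-QC map — the chip coverage that the surviving SNPs
define.

## The synthetic cohort

`simulate_cohort()` is first-class, tested code, not a fixture: every
pipeline stage is validated against cohorts with exact ground truth because
the motivating real dataset is not publicly archived. The default world is
scaled down but keeps the real cohort's shape: 10 breeds × 30 individuals
(the first five breeds form group "AHIP", the rest "WECP"), 18 autosomes ×
300 SNPs at 40 ± 10 kb spacing (≈ 12 Mb per chromosome, ≈ 215 Mb total),
base allele frequencies uniform on [0.05, 0.5].

* **Breed structure.** Each SNP's frequency is split between the two groups
  by ± half of `group_divergence` (default 0.10) with a *random sign per
  SNP*, plus per-breed drift (SD 0.02). Both groups thereby drift away from
  the cohort mean, reproducing the Wahlund-style excess homozygosity that
  makes F_HOM exceed F_ROH on average in structured cohorts — with a fixed
  shift direction, one group would instead move toward p = 0.5 and show
  spuriously negative F_HOM.
* **Autozygosity.** Planted directly as homozygous tracts (one sampled
  haplotype), not via pedigree simulation, so truth is exact. Breed mean
  targets follow a gradient 0.05–0.30, the range of F_ROH reported across
  indigenous and commercial pig breeds; individual targets vary around the
  breed mean with SD `f_star_sd = 0.05`, anchored on the reported
  within-breed dispersions of SNP-based inbreeding (0.04–0.09). Without
  individual variation, within-breed correlations between inbreeding
  estimators would be undefined noise. The realised planted fraction of
  each individual (not the target) is the recorded truth `f*`.
* **Tract lengths** are drawn from the five standard classes with weights
  0.60/0.32/0.08/0/0 — approximately the observed short-class count shares —
  restricted to classes feasible on a 12 Mb chromosome (requesting an
  infeasible class is an error). Tracts have at least 55 SNPs (a small
  margin over the scanner's 50-SNP floor, so every planted tract is in
  principle detectable) and at least a 50-SNP buffer between tracts of one
  individual, so calls stay distinct.
* **Islands** are planted first: carriers are the first
  `floor(carrier_frac × n)` individuals of the breed by index (so truth
  counts are exact), all sharing one haplotype over the interval. Random
  background tracts never overlap a configured island interval of the same
  breed — otherwise background autozygosity would stack on the configured
  carrier fraction and destroy the "controlled incidence" contract.
* **Noise.** Heterozygous genotyping errors inside tracts at rate 0.002 and
  uniform missingness at 0.01.
* **Determinism.** All randomness flows from the single config seed through
  R's default Mersenne-Twister generator; the same seed reproduces the
  cohort byte for byte, including the PLINK files it writes.

What the generator does **not** emulate: linkage disequilibrium and
realistic recombination maps, mutation, selection, pedigree loops, and
array-specific artefacts (batch effects, clustering failures). A green
recovery test therefore establishes the correctness of the scanning and
summarising machinery on an idealised signal, not calibration on real
array data. Two interactions of the idealisation are worth knowing: planted
tracts concentrate homozygote excess at HWE-filtered SNPs more than real
cohorts do (running the default QC before detection would strip ~10% of
SNPs inside tracts), and flanking background SNPs adjoin tracts without the
LD structure that in real data softens the boundary-overrun effect
described above.

## GRM and PCA

`build_grm()` implements the GCTA-style variance-standardised estimator
with per-SNP standardisation — `A_jk = (1/N_jk) Σ (x_ij − 2p_i)(x_ik − 2p_i)
/ (2p_i(1−p_i))` over SNPs non-missing in both samples — using cohort
frequencies; which pooled-vs-per-SNP variant the motivating analysis used is
not stated, so per-SNP is chosen and documented. `grm_pca()` returns top-k
eigenpairs with scores scaled by the square root of the eigenvalue and a
deterministic sign convention (largest-magnitude loading positive), so
results are reproducible across platforms.

## Islands and annotation

Per-breed incidence tracks are thresholded inclusively (`incidence ≥ 0.40`;
the published figure convention is ambiguous, and inclusive bounds are
auditable), with strict map adjacency — one below-threshold SNP splits an
island, and islands never span chromosomes. Group-level SNP sets are unions
over the group's breeds; between-group comparison reports unique and shared
SNP counts. Annotation reads BED (0-based half-open) or GFF3 (1-based
inclusive) through `rtracklayer`, normalises to 1-based inclusive, and
reports every overlap of at least 1 bp in deterministic order; a quadratic
all-pairs scan serves as the test oracle.

## Numerical and degenerate-input conventions

* HWE ties use a relative tolerance of 1e-10 when summing probabilities "no
  more likely than observed".
* Pearson correlations require at least 3 pairs and strictly positive
  variances; breeds failing that report `NA` rather than a value.
* Standard errors are `sd/sqrt(n)`; single observations report `NA`.
* Chromosomes with fewer than two SNPs are excluded from `L_auto` and
  flagged undefined in coverage tables, with warnings.
* All-missing variants are flagged undefined in `allele_stats()` and
  excluded from the GRM with a warning; a sample pair with no jointly
  genotyped SNP is an error.
* An empty ROH set is legal everywhere downstream: tables are emitted with
  zeros and a warning.

## Known limitations

* Boundary overrun of the window-threshold rule, quantified above.
* F_HOM depends on the reference population through `E`; with strong group
  structure it mixes inbreeding with population stratification. This is a
  property of the estimator, reproduced deliberately.
* The QC order (mind → geno → HWE → MAF) affects per-stage removal counts;
  counts are reported per stage and the order is logged in the QC report,
  but removal tallies are not comparable across tools that filter in a
  different order.
* VCF input, sex chromosomes, multi-allelic sites, imputation and
  ancestry-model fitting are out of scope.
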