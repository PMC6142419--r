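---
title: "Quantifying allelic noise in single- and sparse-cell whole-genome-amplified sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying allelic noise in single- and sparse-cell whole-genome-amplified sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Whole-genome amplification (WGA) by multiple displacement amplification
(MDA) makes exome sequencing possible from one or a handful of cells, but it
amplifies the two alleles of a heterozygous site unevenly. The fewer the
input cells, the fewer template molecules per allele, and the more often one
allele is under-amplified (allelic imbalance) or lost outright (allele
dropout). A heterozygous call in one assay may therefore appear homozygous,
carry a different allele, or be absent in a replicate assay from the same
cell population. `mdaqc` implements a replicate-dilution QC strategy for
this setting: amplify and sequence duplicate aliquots at a series of cell
inputs (1, 2, 5, 10, 25, 50 cells), then quantify

1. **replicate allelic mismatch** — the fraction of variant sites not
   concordantly reproduced, classified as loss of heterozygosity (LoH),
   allele change or total dropout, and its decay with cell input;
2. **signal-to-noise ratio (SNR)** of heterozygous variant allele
   frequencies (VAFs) — the mean VAF (the "signal", 1/2 on a copy-neutral
   chromosome) over its standard deviation (the amplification "noise"),
   whose reciprocal is the coefficient of variation (CV);
3. **genotype-likelihood concordance** — Spearman correlation of
   heterozygous-genotype probabilities `P = 10^(-PL/10)` between assays;
4. **STR panel dropout** — full locus dropout, complete LoH and
   peak-imbalance partial dropout over a 21-locus identity panel;
5. **copy-number alterations (CNA) from allelic imbalance** — gains, losses
   and copy-neutral LoH read off the chromosomal VAF distribution, without a
   paired normal control.

Because the measurements that motivated this design are not publicly
deposited, the package ships a forward simulator that generates VCF-format
replicate assays with the statistical structure the analyses assume. The
simulator is first-class, tested code: every analysis in the package can be
exercised, calibrated and regression-tested against known ground truth.

# The generative model

Each variant site on a chromosome carries a zygosity (heterozygous, or
homozygous-alternate with probability `hom_alt_fraction = 0.3`, a typical
exome-wide proportion once common homozygous polymorphisms are included) and
a copy state from the karyotype. Per site and haplotype:

* each input cell contributes one template per haplotype copy (two for the
  duplicated haplotype of a gain, zero for the lost haplotype of a
  deletion);
* a template seeds amplification with probability `template_survival`;
* each surviving template draws an independent Gamma(`gain_shape`)
  amplification gain. Since a sum of `m` iid Gamma(k) variables is
  Gamma(mk), the pooled per-allele gain is a single Gamma draw, and the
  alternate-allele fraction of the amplicon pool is
  `f = G_alt / (G_alt + G_ref)` — a Beta-like quantity whose dispersion
  shrinks as cells increase;
* sequencing draws a negative-binomial total depth (mean 90, matching a
  typical exome design; dispersion 3 gives the heavy depth variability of
  amplified libraries) and binomial alternate reads at
  `f` adjusted by a symmetric per-read miscall rate (0.002);
* genotypes and phred-scaled likelihoods (PL) are the three diploid binomial
  likelihoods, normalized so the best genotype has PL 0 — the standard
  convention of mainstream variant callers;
* sites whose templates all fail, that draw zero depth, or that are called
  homozygous-reference are omitted from the emitted VCF, as in single-sample
  calling; downstream, replicate comparison counts them as dropout.

An optional false-positive process (`fp_rate`, off by default) adds
amplification-artifact variants whose count scales as 1/cells and whose
positions fall mostly outside the coding target regions, emulating the
observation that raw variant counts inflate at low input and that the extra
noise concentrates off-target.

The STR panel uses the same survival/gain mechanism per haplotype of each of
21 loci (18 heterozygous): a haplotype whose templates all fail yields a
peak height of zero.

## The default karyotype

The default genome emulates a leukemia cell line with a complex karyotype,
scaled to desk size (3,900 variant sites over 8 chromosomes):
whole-chromosome trisomies of chr5 and chr8; a large p-arm loss (sites
1–320 of 700, ~46%, a realistic p-arm share) plus a q-arm gain on chr1; a
small interstitial deletion on chr13 spanning 80 sites — deliberately below
the 100-variant median-filter scale, to reproduce a documented
false-negative mode; a q-arm gain on chr17; copy-neutral LoH on chr19q; and
two fully neutral chromosomes (chr2, chr3) reserved as the noise reference.
Three driver mutations (DNMT3A R882C, NRAS Q61L as SNVs, the NPM1 W288fs
4-bp insertion) are always-heterozygous flagged sites; the indel exercises
the I/O path but is excluded from SNV mismatch statistics.

CNA segments are expressed in variant ordinals, not base pairs, because the
median filter and the window caller operate over variant neighborhoods.

## Calibration of the defaults

The model parameters are calibration knobs; their defaults
(`template_survival = 0.9`, `gain_shape = 1.0`) were fixed once, by a sweep
over candidate values, so that the simulated study conditions reproduce the
qualitative behavior the analyses are designed to detect:

* single-cell replicate SNV mismatch in the 0.3–0.5 range, decaying
  approximately exponentially with cell input;
* SNR(50 cells) / SNR(1 cell) at least 2, with SNR roughly log-linear in
  cell input;
* heterozygous VAFs approximately normal at 50 cells (Anderson–Darling) but
  clearly non-normal at 1 cell;
* whole-chromosome gains detectable from 5 cells up but not from single
  cells, losses detectable down to single cells;
* a median of several affected STR loci (of 21) at single-cell input and
  none at 25–50 cells.

Smaller gain shapes (heavier-tailed amplification) push the single-cell
allele-fraction distribution toward an extreme U-shape and overshoot the
mismatch band; the chosen values sit comfortably inside all the goals at
once. These defaults are the package's study conditions and are not
adjusted per analysis.

# Analysis methods and their parameters

## Filters

All analyses run on PASS calls. The depth threshold is DP ≥ 30 (inclusive),
applied to SNR and CNA analyses; region restriction uses BED conventions
(0-based half-open intervals) against 1-based VCF positions. Filters
commute, and region restriction is idempotent.

## Replicate mismatch

The comparison universe is the **union** of non-reference sites of the two
replicates, keyed by chromosome and position. A one-sided site is a total
dropout; a shared site with different alternate alleles is an allele
change; heterozygous in one and homozygous-alternate in the other is LoH;
otherwise concordant. The union definition makes total dropout expressible;
the two one-directional fractions (share of each replicate's own calls not
reproduced) are also reported. Homozygous-reference calls are excluded —
single-sample VCFs do not emit them. Indels pass through I/O but are
excluded from the SNV mismatch statistic by default.

The mismatch-vs-cells curve is fitted as `y = a·exp(−b·x) + c` with
`a, b, c ≥ 0` by bounded Levenberg–Marquardt with multi-starts over decay
rates; the floor `c` accommodates the non-zero plateau at high input.
Constant data degenerate gracefully to `a ≈ 0, c ≈ mean`.

## SNR and normality

`SNR = μ/σ` with σ the sample (n−1) standard deviation of heterozygous VAFs
on user-designated CNA-free chromosomes (default chr2/chr3). The
chromosomes are user-specified rather than auto-selected to avoid
circularity with the CNA caller. Normality uses the composite
Anderson–Darling test (mean and variance estimated), pass = not rejected at
α = 0.05. The trend is OLS of SNR on ln(cells); per-replicate SNRs are the
default (rather than pooling replicates before estimating σ), so replicate
scatter is visible in the trend fit.

## CNA from allelic imbalance

The caller never uses read-depth ratios (no paired control is assumed) and
cannot distinguish a one-copy loss from copy-neutral LoH — both present as
disappearance of heterozygosity — so the single class `loss_or_cnloh` is
reported.

Pipeline per chromosome, optionally on replicate-mean VAFs:

1. **Mirror** heterozygous VAFs below 0.5 to the equal distance above
   (v → 1−v), pooling the symmetric imbalance signal.
2. **Median filter** over a neighborhood of 100 variants (half-width 50,
   truncated at chromosome ends, never crossing chromosomes).
3. **Gain test**: the mean of the filtered mirrored track is compared with
   `m0 + z·s0/√n_het` (default z = 3), where `m0` and `s0` are the mean and
   SD of the *neutral chromosomes'* mirrored heterozygous VAFs. Mirroring
   folds the distribution, so even a neutral chromosome sits above 0.5 by
   about `σ·√(2/π)`; centering the threshold at the neutral chromosomes' own
   folded level — rather than at 0.5 — is what makes the test calibrated to
   the sample's own noise. The mean (not the median) of the folded values is
   used because it separates a shifted folded distribution better and has
   the plain √n standard error. Whole-chromosome calls use the chromosome's
   `n_het`; windowed calls (100 variants, stride 50) use √window.
4. **Loss test**: the fraction of all VAFs in the mid-range [0.2, 0.8] is
   compared against `loss_factor` (default 1/3) times the neutral
   chromosomes' own mid-range fraction — heterozygosity disappears from a
   lost or copy-neutral-LoH region, leaving VAFs piled near 1.
   Sub-chromosomal losses require a run of ≥ 2 consecutive depleted windows,
   so events spanning fewer than ~100 variants are *not* called: this is the
   sensitivity cost of smoothing at the 100-variant scale, and the small
   chr13 deletion in the default genome documents exactly this false
   negative.
5. **KDE corroboration**: a Gaussian kernel density over the chromosome's
   VAFs, bandwidth from Silverman's rule `h = (4σ⁵/(3n))^(1/5)`, evaluated
   as an exact kernel sum on 512 grid points over [−0.1, 1.1] (margins so
   boundary modes at 0 and 1 are resolved). Mode count uses topographic
   prominence ≥ 0.1 of the global maximum. A disomic chromosome is bimodal
   (hets at 1/2, hom-alt at 1); a trisomy is trimodal (1/3, 2/3, 1). Mode
   counts are reported as evidence alongside the calls; both the raw
   density and a peak-scaled copy (maximum normalized to 1, for relative
   display) are retained.

## Numerical choices and degenerate inputs

* `vaf` is undefined (NA with a warning) at zero allelic depth — never 0.
* SNR is undefined at σ = 0; the normality test rejects constant input and
  requires n ≥ 8; the bandwidth requires n ≥ 2 and σ > 0.
* The Silverman formula is read as `(4σ⁵/(3n))^(1/5)` — the standard
  grouping.
* The exponential fit reports non-convergence explicitly rather than
  failing silently; ties in Spearman correlation use average ranks.
* PL values are capped at 99,999 to avoid infinities when a likelihood
  underflows.
* Genotype-likelihood ties resolve toward the later genotype in
  (hom-ref, het, hom-alt) order; ties are vanishingly rare at depth ~90.

# What the simulation does and does not show

The generator reproduces the *statistical* structure the analyses assume:
cell-count-dependent dropout, heavy-tailed allelic imbalance, depth
overdispersion, karyotype-driven VAF shifts, and off-target artifact
variants. It does not simulate reads, alignment, GC or mappability bias,
chimeric MDA artifacts, index hopping, or locus-specific amplification
efficiency — so passing tests demonstrate that the *analyses* behave
correctly on data with the assumed structure, not that real MDA libraries
have exactly this structure. On real data the mismatch floor, the SNR
scale, and the gain-detection threshold multiplier may all differ; the
package exposes them as parameters for exactly that reason.

Problem sizes were chosen for fast, deterministic checks: 3,900 sites over
8 chromosomes, two replicates at each of six cell inputs, and ten Monte
Carlo seeds for the property checks. These sizes make every distributional
property stable without requiring genome-scale data.

# Known limitations

* Whole-chromosome and windowed segment calls only; no breakpoint-precise
  segmentation, and translocations are visible only through their copy
  imbalance.
* Losses and copy-neutral LoH are inherently indistinguishable from allele
  frequencies alone; resolving them needs karyotyping or read-depth ratios
  with a paired control.
* The STR partial-dropout peak-ratio threshold (default 3) is a convention;
  fragment-analysis practice varies.
* `analyze` mode expects single-sample VCFs with GT/AD/DP/PL; multi-allelic
  records are skipped with a warning rather than decomposed.
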