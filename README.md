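# mdaqc — quality assessment for single- and sparse-cell WGA sequencing

Sequencing one or a handful of cells requires whole-genome amplification
(WGA, typically multiple displacement amplification), and amplification from
so few template molecules distorts the two alleles of a heterozygous site:
alleles drop out, allele frequencies disperse, and a variant confidently
called in one assay may be missing or homozygous in a replicate. `mdaqc` is
an R package for quantifying exactly how bad that is in a given setup, using
a replicate serial-dilution design (duplicate assays at 1, 2, 5, 10, 25 and
50 cells), and for extracting what is still reliably recoverable — driver
genotypes and large copy-number alterations — from the allelic signal alone.

It is aimed at groups running or evaluating single-cell DNA-seq QC: it takes
single-sample VCFs (GT, AD, DP, PL) and computes, per cell input,

* **replicate allelic mismatch** — per-site classification into concordant /
  loss of heterozygosity / allele change / total dropout over the union of
  called sites, and the decay of the mismatch fraction with cell input,
  fitted as `y = a·e^(−bx) + c` (a, b, c ≥ 0);
* **signal-to-noise ratio** of heterozygous variant allele frequencies on
  copy-neutral chromosomes: `SNR = μ/σ` (reciprocal of the coefficient of
  variation), with a composite Anderson–Darling normality check and a
  log-linear SNR-vs-ln(cells) trend;
* **genotype-likelihood concordance** — Spearman ρ of the heterozygous
  genotype probability `P = 10^(−PL/10)` across assays;
* **STR identity-panel dropout** — full locus dropout, complete LoH, and
  peak-height-imbalance partial dropout over a 21-locus panel;
* **CNA / LoH from allelic imbalance** (no paired control needed): mirror
  het VAFs about 0.5, median-filter over 100-variant neighborhoods, test
  the smoothed level against the neutral chromosomes' own noise for gains,
  test mid-range-VAF depletion for losses / copy-neutral LoH, and
  corroborate with Gaussian-KDE modality (Silverman bandwidth
  `h = (4σ⁵/3n)^{1/5}`): disomy is bimodal (1/2, 1), trisomy trimodal
  (1/3, 2/3, 1).

Because no raw data for this design is publicly deposited, the package
includes a calibrated forward simulator (`build_genome()`,
`simulate_assay()`, `simulate_str_panel()`, `write_fixture_set()`) that
emulates a leukemia cell line with a complex karyotype — trisomies 5 and 8,
del(1p) + dup(1q), a small del(13) below the filter scale, dup(17q),
copy-neutral LoH on 19q — with template-level survival and Gamma
amplification gains, so every analysis is testable against ground truth.
See the methods vignette (`vignettes/sparse-cell-noise.Rmd`) for the model
and all parameter choices.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Step 1
simulates the dilution series to `results/fixtures/`; steps 2–4 analyze it;
step 5 renders a machine-readable QC report.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_concordance.R
```

Step 2 prints (seed 1):

```
Mismatch fraction by cell input:
 cell_count    mismatch n_pairs
          1 0.314965035       1
          2 0.172300082       1
          5 0.032249248       1
         10 0.008745559       1
         25 0.003551913       1
         50 0.003005464       1
Exponential decay fit: 0.571 * exp(-0.612 x) + 0.005  (R^2 = 1.000)
Heterozygous-likelihood Spearman rho vs 50-cell anchor: 0.73-0.92
```

Read: ~31% of SNVs called in one single-cell assay are not concordantly
reproduced in its duplicate (mostly as apparent LoH), the discrepancy falls
off approximately exponentially with cell input and is negligible by 25–50
cells, and genotype likelihoods of low-input assays correlate only
moderately with the 50-cell anchor. Step 3 shows the same story as noise:

```
Log-linear trend: SNR = 1.78 + 1.05 * ln(cells)  (R^2 = 0.95)
SNR(50) / SNR(1) = 2.72
```

with het-VAF dispersion σ shrinking from ≈0.22 (1 cell) to ≈0.08 (50
cells) and the Anderson–Darling test accepting normality only for the
higher inputs. Step 4 calls the karyotype from allelic imbalance alone:

```
 1 cells: loss_or_cnloh(chr1:1-200) loss_or_cnloh(chr19:201-350)
 5 cells: gain(chr1:whole) loss_or_cnloh(chr1:1-200) gain(chr17:148-383)
          loss_or_cnloh(chr19:201-350) gain(chr5:whole) gain(chr8:whole)
chr8 at 50 cells: 3 modes at 0.33, 0.65, 1 (Silverman h = 0.082)
chr2 at 50 cells: 2 modes at 0.5, 1 (Silverman h = 0.081)
```

Losses and copy-neutral LoH are recovered down to a single cell; gains need
≥ 5 cells; the 80-variant del(13) is missed at every input — the documented
cost of smoothing at the 100-variant scale. Equivalent one-shot runs:
`run_pipeline(pipeline_config(mode = "simulate", seed = 1))`, or
`mode = "analyze"` with a sample table of your own VCFs.

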