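#!/usr/bin/env Rscript
# Step 1: forward-simulate the dilution series.
#
# Generates the study's replicate design — 1, 2, 5, 10, 25 and 50 cells, two
# replicates each — from the default leukemia-like genome (trisomies 5 and 8,
# del(1p) + dup(1q), a small del(13), dup(17q), copy-neutral LoH on 19q,
# neutral chr2/chr3), and writes the VCFs, STR tables, coding BED and truth
# sidecar under results/fixtures/.

suppressPackageStartupMessages(library(mdaqc))

seed <- 1L
out <- "results/fixtures"

cfg <- simulation_config(seed = seed)
manifest <- write_fixture_set(cfg, out)

genome <- cfg$genome
cat(sprintf("Simulated genome: %d variant sites on %d chromosomes\n",
            nrow(genome$sites), length(genome$chromosomes)))
cat(sprintf("  karyotype segments: %s\n",
            paste(sprintf("%s[%d-%d]:%s", genome$segments$chrom,
                          genome$segments$start, genome$segments$end,
                          genome$segments$state), collapse = ", ")))
cat(sprintf("Wrote %d single-sample VCFs (+ STR panel, BED, truth sidecar) to %s\n",
            nrow(manifest$samples), out))
cat("Model:", sprintf("survival=%.2f gain_shape=%.2f error=%.3f depth=%g disp=%g",
    cfg$model$template_survival, cfg$model$gain_shape,
    cfg$model$sequencing_error, cfg$model$mean_depth,
    cfg$model$depth_dispersion), "\n")
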