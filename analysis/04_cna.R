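#!/usr/bin/env Rscript
# Step 4: copy-number / LoH detection from allelic imbalance.
#
# For each cell count (using replicate-mean VAFs of the duplicate assays):
# mirror het VAFs, median-filter over 100-variant neighborhoods, call gains
# against the neutral chromosomes' own noise, call losses / copy-neutral LoH
# from mid-range VAF depletion, and record the KDE mode structure (bimodal
# disomy vs trimodal trisomy). Tables land in results/cna/.

suppressPackageStartupMessages(library(mdaqc))

fixtures <- "results/fixtures"
if (!file.exists(file.path(fixtures, "manifest.json")))
  stop("run analysis/01_simulate.R first", call. = FALSE)
out <- "results/cna"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

manifest <- jsonlite::fromJSON(file.path(fixtures, "manifest.json"))
samples <- manifest$samples

all_calls <- list()
for (cc in sort(unique(samples$cell_count))) {
  pair <- samples[samples$cell_count == cc, ]
  a <- filter_pass(read_vcf(file.path(fixtures, pair$path[1]),
                            cell_count = cc, replicate_index = 1L))
  b <- filter_pass(read_vcf(file.path(fixtures, pair$path[2]),
                            cell_count = cc, replicate_index = 2L))
  calls <- call_cna(a, replicate_b = b)
  calls <- cbind(data.frame(cell_count = cc), calls)
  all_calls[[as.character(cc)]] <- calls
  hit <- calls[calls$call != "neutral", c("chrom", "segment", "call")]
  cat(sprintf("%2d cells: %s\n", cc,
              if (nrow(hit)) paste(sprintf("%s(%s:%s)", hit$call, hit$chrom,
                                           hit$segment), collapse = " ")
              else "no aberration called"))
}
calls <- do.call(rbind, all_calls)
write.table(calls, file.path(out, "cna_calls.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

# KDE mode structure of the trisomy vs a neutral chromosome at 50 cells
pair <- samples[samples$cell_count == 50L, ]
a50 <- filter_pass(read_vcf(file.path(fixtures, pair$path[1]),
                            cell_count = 50L))
dens <- do.call(rbind, lapply(c("chr8", "chr2"), function(ch) {
  s <- chrom_vaf_series(a50, ch)
  prof <- kde(s$vaf)
  modes <- detect_modes(prof)
  cat(sprintf("%s at 50 cells: %d modes at %s (Silverman h = %.3f)\n", ch,
              modes$count, paste(round(modes$locations, 2), collapse = ", "),
              prof$h))
  data.frame(chrom = ch, vaf = prof$grid, density = prof$density,
             density_scaled = prof$density_scaled)
}))
write.table(dens, file.path(out, "kde_profiles_50cell.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
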