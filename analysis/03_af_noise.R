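#!/usr/bin/env Rscript
# Step 3: heterozygous allele-frequency noise.
#
# On the copy-neutral chromosomes (chr2, chr3; depth >= 30) computes per
# assay the mean, dispersion, SNR = mu/sigma and CV of heterozygous VAFs,
# the Anderson-Darling normality check, and the log-linear SNR trend over
# cell input. Tables land in results/af_noise/.

suppressPackageStartupMessages(library(mdaqc))

fixtures <- "results/fixtures"
if (!file.exists(file.path(fixtures, "manifest.json")))
  stop("run analysis/01_simulate.R first", call. = FALSE)
out <- "results/af_noise"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

manifest <- jsonlite::fromJSON(file.path(fixtures, "manifest.json"))
samples <- manifest$samples

tab <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
  r <- filter_pass(read_vcf(file.path(fixtures, samples$path[i]),
                            cell_count = samples$cell_count[i],
                            replicate_index = samples$replicate[i]))
  v <- het_af_values(r, c("chr2", "chr3"), min_depth = 30)
  s <- compute_snr(v)
  nt <- test_normality(v)
  data.frame(sample = r$sample_id, cell_count = r$cell_count, n = s$n,
             mu = s$mu, sigma = s$sigma, snr = s$snr, cv = s$cv,
             ad_statistic = nt$statistic, ad_p = nt$p_value,
             normal = nt$pass)
}))
tab <- tab[order(tab$cell_count), ]
write.table(tab, file.path(out, "snr_by_assay.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("Heterozygous-AF noise by assay (neutral chromosomes 2 and 3):\n")
print(tab, row.names = FALSE, digits = 3)

trend <- snr_trend(tab$cell_count, tab$snr)
cat(sprintf("\nLog-linear trend: SNR = %.2f + %.2f * ln(cells)  (R^2 = %.2f)\n",
            trend$intercept, trend$slope, trend$r_squared))
cat(sprintf("SNR(50) / SNR(1) = %.2f\n", trend$ratio_max_min))
write.table(data.frame(slope = trend$slope, intercept = trend$intercept,
                       r_squared = trend$r_squared,
                       ratio_max_min = trend$ratio_max_min),
            file.path(out, "snr_trend.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
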