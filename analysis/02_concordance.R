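#!/usr/bin/env Rscript
# Step 2: replicate concordance.
#
# For each cell count, classifies every unioned variant site of the two
# replicates as concordant / LoH / allele change / total dropout, fits the
# mismatch-vs-cells decay as a * exp(-b x) + c, correlates each assay's
# heterozygous genotype likelihoods (P = 10^(-PL/10)) against the 50-cell
# anchor replicate, and scores the STR panel. Tables land in
# results/concordance/.

suppressPackageStartupMessages(library(mdaqc))

fixtures <- "results/fixtures"
if (!file.exists(file.path(fixtures, "manifest.json")))
  stop("run analysis/01_simulate.R first", call. = FALSE)
out <- "results/concordance"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

manifest <- jsonlite::fromJSON(file.path(fixtures, "manifest.json"))
samples <- manifest$samples
reps <- lapply(seq_len(nrow(samples)), function(i)
  filter_pass(read_vcf(file.path(fixtures, samples$path[i]),
                       cell_count = samples$cell_count[i],
                       replicate_index = samples$replicate[i])))
cells <- vapply(reps, function(r) r$cell_count, 1L)

summaries <- list()
for (cc in sort(unique(cells))) {
  pair <- reps[cells == cc]
  summaries[[as.character(cc)]] <- mismatch_fraction(pair[[1]], pair[[2]])
}
curve <- mismatch_curve(summaries)
fit <- fit_exponential(curve$cell_count, curve$mismatch)

cat("Mismatch fraction by cell input:\n")
print(curve, row.names = FALSE)
cat(sprintf("Exponential decay fit: %.3f * exp(-%.3f x) + %.3f  (R^2 = %.3f)\n",
            fit$a, fit$b, fit$c, fit$r_squared))

mismatch_tab <- do.call(rbind, lapply(summaries, function(s)
  data.frame(cell_count = s$cell_count, n_sites = s$n_sites,
             concordant = s$counts$concordant, loh = s$counts$loh,
             allele_change = s$counts$allele_change,
             total_dropout = s$counts$total_dropout,
             mismatch = s$mismatch_fraction,
             directional_a = s$directional_a,
             directional_b = s$directional_b)))
write.table(mismatch_tab, file.path(out, "mismatch_by_cells.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

# genotype-likelihood correlation vs the 50-cell anchor
anchor <- reps[[which(cells == 50L)[1]]]
gl <- do.call(rbind, lapply(reps, function(r) {
  if (identical(r$sample_id, anchor$sample_id)) return(NULL)
  res <- genotype_likelihood_correlation(r, anchor)
  data.frame(sample = r$sample_id, cell_count = r$cell_count,
             rho = res$rho, n_shared = res$n_shared)
}))
write.table(gl, file.path(out, "gl_correlation.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("Heterozygous-likelihood Spearman rho vs 50-cell anchor: %.2f-%.2f\n",
            min(gl$rho), max(gl$rho)))

# STR panel dropout per assay
str_obs <- read.delim(file.path(fixtures, "str_panel.tsv"))
str_ref <- read.delim(file.path(fixtures, "str_reference.tsv"))
str_tab <- do.call(rbind, lapply(split(str_obs,
                                       list(str_obs$cell_count, str_obs$replicate)),
                                 function(obs) {
  cmp <- compare_str(str_ref, obs, imbalance_ratio_threshold = 3)
  data.frame(cell_count = obs$cell_count[1], replicate = obs$replicate[1],
             n_affected = cmp$n_affected,
             full_dropout = sum(cmp$comparisons$status == "full_dropout"),
             complete_loh = sum(cmp$comparisons$status == "complete_loh"),
             partial_dropout = sum(cmp$comparisons$status == "partial_dropout"))
}))
str_tab <- str_tab[order(str_tab$cell_count, str_tab$replicate), ]
write.table(str_tab, file.path(out, "str_dropout.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("STR loci affected (of 21) by cell input:\n")
print(str_tab, row.names = FALSE)
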