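# Builders for small in-code fixtures used across the test files.

# one call row with sensible defaults
mk_call <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                    genotype = "het", ad_ref = 20L, ad_alt = 20L,
                    dp = ad_ref + ad_alt, pl_hom_ref = 99L, pl_het = 0L,
                    pl_hom_alt = 99L, filter = "PASS") {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             genotype = genotype, ad_ref = as.integer(ad_ref),
             ad_alt = as.integer(ad_alt), dp = as.integer(dp),
             pl_hom_ref = as.integer(pl_hom_ref), pl_het = as.integer(pl_het),
             pl_hom_alt = as.integer(pl_hom_alt), filter = filter,
             stringsAsFactors = FALSE)
}

mk_replicate <- function(..., sample_id = "toy", cell_count = NA_integer_,
                         replicate_index = 1L) {
  rows <- list(...)
  calls <- if (length(rows)) do.call(rbind, rows) else
    mk_call()[0, , drop = FALSE]
  assay_replicate(calls, sample_id = sample_id, cell_count = cell_count,
                  replicate_index = replicate_index)
}

# a small genome + the calibrated model, shared by simulation tests
test_genome <- function(seed = 1L) build_genome(seed = seed)
test_model <- function(...) amplification_model(...)
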