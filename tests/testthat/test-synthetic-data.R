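# Forward simulator: genome construction, amplification model behavior,
# STR panel generation and fixture writing.

test_that("genome with no CNA segments is fully neutral", {
  spec <- default_genome_spec()
  spec$cna <- spec$cna[0, ]
  spec$drivers <- spec$drivers[0, ]
  g <- build_genome(spec, seed = 3L)
  expect_true(all(g$sites$copy_state == "neutral"))
  expect_true(all(g$sites$truth_genotype %in% c("het", "hom_alt")))
})

test_that("genome construction is deterministic given (spec, seed)", {
  g1 <- build_genome(seed = 11L)
  g2 <- build_genome(seed = 11L)
  expect_identical(g1$sites, g2$sites)
  expect_identical(g1$segments, g2$segments)
  g3 <- build_genome(seed = 12L)
  expect_false(identical(g1$sites$pos, g3$sites$pos))
})

test_that("default genome has exactly one small loss segment and the karyotype anchors", {
  g <- build_genome(seed = 1L)
  loss <- g$segments[g$segments$state == "loss", ]
  het_in_seg <- vapply(seq_len(nrow(loss)), function(i) {
    s <- g$sites[g$sites$chrom == loss$chrom[i] &
                 g$sites$index >= loss$start[i] & g$sites$index <= loss$end[i], ]
    sum(s$zygosity == "het")
  }, 1L)
  expect_identical(sum(het_in_seg < 100), 1L)      # the del(13) analogue
  expect_true(any(het_in_seg >= 100))              # and a large loss
  expect_true(any(g$segments$state == "gain"))
  expect_true(any(g$segments$state == "cn_loh"))
  # two fully neutral chromosomes reserved for noise estimation
  neutral <- setdiff(names(g$chromosomes), unique(g$segments$chrom))
  expect_true(all(c("chr2", "chr3") %in% neutral))
  # positions strictly increasing, drivers heterozygous
  for (ch in names(g$chromosomes)) {
    expect_true(all(diff(g$sites$pos[g$sites$chrom == ch]) > 0))
  }
  drv <- g$sites[!is.na(g$sites$driver), ]
  expect_identical(nrow(drv), 3L)
  expect_true(all(drv$truth_genotype == "het"))
  expect_identical(nrow(g$str_loci), 21L)
  expect_identical(sum(g$str_loci$het), 18L)
})

test_that("overlapping CNA segments are rejected with the segments named", {
  spec <- default_genome_spec()
  spec$cna <- rbind(cna_segment("chr8", 1L, 300L, "gain"),
                    cna_segment("chr8", 250L, 400L, "loss"))
  spec$drivers <- spec$drivers[0, ]
  expect_error(build_genome(spec, seed = 1L), "overlapping.*chr8")
})

test_that("large cell input recovers balanced alleles at neutral het sites", {
  g <- test_genome()
  m <- test_model()
  a <- simulate_assay(g, m, 10000L, seed = 5L)
  idx <- g$sites$chrom %in% c("chr2", "chr3") & g$sites$zygosity == "het"
  key <- paste(g$sites$chrom[idx], g$sites$pos[idx])
  calls <- a$calls[paste(a$calls$chrom, a$calls$pos) %in% key, ]
  v <- suppressWarnings(vaf(calls$ad_ref, calls$ad_alt))
  expect_lt(abs(mean(v) - 0.5), 0.02)
})

test_that("deterministic amplification (s = 1, huge gain shape, no error) gives f near 0.5", {
  g <- test_genome()
  m <- amplification_model(template_survival = 1, gain_shape = 1000,
                           sequencing_error = 0, mean_depth = 2000,
                           depth_dispersion = 500)
  a <- simulate_assay(g, m, 5L, seed = 9L)
  idx <- g$sites$chrom %in% c("chr2", "chr3") & g$sites$zygosity == "het"
  key <- paste(g$sites$chrom[idx], g$sites$pos[idx])
  calls <- a$calls[paste(a$calls$chrom, a$calls$pos) %in% key, ]
  v <- suppressWarnings(vaf(calls$ad_ref, calls$ad_alt))
  expect_true(all(abs(v - 0.5) < 0.05))
})

test_that("both alleles are observed more often at 50 cells than at 1 (10 seeds)", {
  g <- test_genome()
  m <- test_model()
  het_key <- with(g$sites[g$sites$truth_genotype == "het", ], paste(chrom, pos))
  frac_both <- function(a) {
    calls <- a$calls[paste(a$calls$chrom, a$calls$pos) %in% het_key, ]
    sum(calls$genotype == "het") / length(het_key)
  }
  for (sd in 1:10) {
    f1 <- frac_both(simulate_assay(g, m, 1L, seed = 100 + sd))
    f50 <- frac_both(simulate_assay(g, m, 50L, seed = 200 + sd))
    expect_gt(f50, f1)
  }
})

test_that("simulation rejects non-positive cell counts", {
  g <- test_genome()
  expect_error(simulate_assay(g, test_model(), 0L, seed = 1L), "positive")
  expect_error(simulate_str_panel(g, test_model(), -1L, seed = 1L), "positive")
})

test_that("gain segments shift het VAFs away from 0.5 at high input", {
  g <- test_genome()
  a <- simulate_assay(g, test_model(), 50L, seed = 21L)
  sites <- g$sites
  pick <- function(state) {
    idx <- sites$copy_state == state & sites$truth_genotype == "het"
    key <- paste(sites$chrom[idx], sites$pos[idx])
    calls <- a$calls[paste(a$calls$chrom, a$calls$pos) %in% key &
                     a$calls$genotype == "het", ]
    abs(suppressWarnings(vaf(calls$ad_ref, calls$ad_alt)) - 0.5)
  }
  dev_gain <- pick("gain")
  dev_neutral <- pick("neutral")
  expect_lt(t.test(dev_gain, dev_neutral, alternative = "greater")$p.value, 0.01)
})

test_that("perfect amplification leaves the STR panel intact", {
  g <- test_genome()
  m <- amplification_model(template_survival = 1, gain_shape = 1000,
                           sequencing_error = 0)
  obs <- simulate_str_panel(g, m, 5L, seed = 2L)
  cmp <- compare_str(g$str_loci, obs, imbalance_ratio_threshold = 3)
  expect_identical(cmp$n_affected, 0L)
  expect_identical(sum(obs$height1 == 0 & g$str_loci$het), 0L)
})

test_that("single-cell STR runs drop loci (median over 50 seeds) and hom loci are never LoH", {
  g <- test_genome()
  m <- test_model()
  affected <- vapply(1:50, function(sd) {
    obs <- simulate_str_panel(g, m, 1L, seed = sd)
    cmp <- compare_str(g$str_loci, obs, 3)
    # homozygous loci must never be classified as loss of heterozygosity
    expect_identical(
      sum(cmp$comparisons$status %in% c("complete_loh", "partial_dropout") &
          !cmp$comparisons$het), 0L)
    cmp$n_affected
  }, 1L)
  expect_gt(median(affected), 0)
})

test_that("fixture sets round-trip through VCF and record driver truth", {
  cfg <- simulation_config(cell_counts = c(1L, 5L, 50L), seed = 4L,
                           genome = test_genome())
  out <- tempfile("fixtures")
  manifest <- write_fixture_set(cfg, out)
  vcfs <- list.files(out, pattern = "\\.vcf$")
  expect_identical(length(vcfs), 6L)  # 3 cell counts x 2 replicates
  expect_identical(nrow(manifest$samples), 6L)
  # round trip
  one <- manifest$samples[1, ]
  back <- read_vcf(file.path(out, one$path), cell_count = one$cell_count,
                   replicate = one$replicate)
  orig <- simulate_fixture_set(cfg)$replicates[[sub("\\.vcf$", "", one$path)]]
  expect_equal(back$calls, orig$calls)
  # driver sites are heterozygous in the truth sidecar
  truth <- read.delim(file.path(out, "truth_sites.tsv"))
  expect_true(all(truth$truth_genotype[!is.na(truth$driver)] == "het"))
  unlink(out, recursive = TRUE)
})

test_that("identical configuration and seed give byte-identical VCFs", {
  cfg <- simulation_config(cell_counts = c(1L, 5L), seed = 8L,
                           genome = test_genome())
  d1 <- tempfile(); d2 <- tempfile()
  write_fixture_set(cfg, d1)
  write_fixture_set(cfg, d2)
  for (f in list.files(d1, pattern = "\\.vcf$")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("off-target false positives inflate mismatch outside coding regions only", {
  g <- test_genome()
  m <- amplification_model(fp_rate = 300)
  bed <- coding_regions(g)
  for (sd in 1:3) {
    a <- simulate_assay(g, m, 1L, seed = 500 + sd)
    b <- simulate_assay(g, m, 1L, seed = 600 + sd, replicate_index = 2L)
    raw <- mismatch_fraction(a, b)$mismatch_fraction
    coding <- mismatch_fraction(restrict_to_regions(a, bed),
                                restrict_to_regions(b, bed))$mismatch_fraction
    expect_lte(coding, raw)
  }
})
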