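# Replicate concordance: pair classification, mismatch summaries, the
# exponential decay fit, likelihood correlation, STR scoring and overlap.

test_that("site pairs classify into the four reproducibility classes", {
  het_g <- mk_call(genotype = "het", alt = "G")
  het_t <- mk_call(genotype = "het", alt = "T")
  hom_g <- mk_call(genotype = "hom_alt", alt = "G")
  expect_identical(classify_site_pair(het_g, het_g), "concordant")
  expect_identical(classify_site_pair(hom_g, hom_g), "concordant")
  expect_identical(classify_site_pair(het_g, hom_g), "loh")
  expect_identical(classify_site_pair(hom_g, het_g), "loh")
  expect_identical(classify_site_pair(het_g, het_t), "allele_change")
  expect_identical(classify_site_pair(het_g, NULL), "total_dropout")
  expect_identical(classify_site_pair(NULL, hom_g), "total_dropout")
  expect_error(classify_site_pair(NULL, NULL), "universe")
})

test_that("mismatch fraction matches hand enumeration on toy sets", {
  # identical replicates: fraction 0
  a <- mk_replicate(mk_call(pos = 1), mk_call(pos = 2), mk_call(pos = 3))
  expect_equal(mismatch_fraction(a, a)$mismatch_fraction, 0)
  # 4 sites: 2 concordant, 1 loh, 1 total dropout -> 0.5
  b1 <- mk_replicate(mk_call(pos = 1), mk_call(pos = 2),
                     mk_call(pos = 3, genotype = "het"),
                     mk_call(pos = 4))
  b2 <- mk_replicate(mk_call(pos = 1), mk_call(pos = 2),
                     mk_call(pos = 3, genotype = "hom_alt"))
  s <- mismatch_fraction(b1, b2)
  expect_identical(s$n_sites, 4L)
  expect_identical(s$counts$concordant, 2L)
  expect_identical(s$counts$loh, 1L)
  expect_identical(s$counts$total_dropout, 1L)
  expect_equal(s$mismatch_fraction, 0.5)
  # one empty side: all dropout
  empty <- mk_replicate()
  s2 <- mismatch_fraction(empty, a)
  expect_equal(s2$mismatch_fraction, 1.0)
  expect_identical(s2$counts$total_dropout, 3L)
  # both empty: undefined
  expect_error(mismatch_fraction(empty, empty), "empty")
})

test_that("mismatch fraction is symmetric and class counts conserve", {
  set.seed(7)
  mk_random_rep <- function() {
    rows <- lapply(sample(1:30, 18), function(p)
      mk_call(pos = p, genotype = sample(c("het", "hom_alt"), 1),
              alt = sample(c("G", "T"), 1)))
    mk_replicate(do.call(rbind, rows)[!duplicated(sapply(rows, `[[`, "pos")), ])
  }
  for (i in 1:10) {
    a <- mk_random_rep(); b <- mk_random_rep()
    sa <- mismatch_fraction(a, b); sb <- mismatch_fraction(b, a)
    expect_equal(sa$mismatch_fraction, sb$mismatch_fraction)
    expect_identical(Reduce(`+`, sa$counts), sa$n_sites)
  }
})

test_that("indels are excluded from the SNV mismatch statistic by default", {
  a <- mk_replicate(mk_call(pos = 1), mk_call(pos = 2, ref = "T", alt = "TCTG"))
  b <- mk_replicate(mk_call(pos = 1))
  expect_identical(mismatch_fraction(a, b)$n_sites, 1L)
  expect_identical(mismatch_fraction(a, b, snvs_only = FALSE)$n_sites, 2L)
})

test_that("the mismatch curve aggregates pairs per cell count", {
  s1 <- mismatch_fraction(
    mk_replicate(mk_call(pos = 1), mk_call(pos = 2), cell_count = 1L),
    mk_replicate(mk_call(pos = 1), cell_count = 1L))       # 0.5
  s2 <- mismatch_fraction(
    mk_replicate(mk_call(pos = 1), cell_count = 5L),
    mk_replicate(mk_call(pos = 1), cell_count = 5L))       # 0
  curve <- mismatch_curve(list(s1, s2))
  expect_identical(nrow(curve), 2L)
  expect_equal(curve$mismatch, c(0.5, 0))
  # ties averaged
  s1b <- mismatch_fraction(
    mk_replicate(mk_call(pos = 1), cell_count = 1L),
    mk_replicate(mk_call(pos = 1), cell_count = 1L))       # 0
  curve2 <- mismatch_curve(list(s1, s1b, s2))
  expect_equal(curve2$mismatch[curve2$cell_count == 1], 0.25)
  expect_identical(curve2$n_pairs[curve2$cell_count == 1], 2L)
})

test_that("replicates with different cell counts are rejected", {
  a <- mk_replicate(mk_call(), cell_count = 1L)
  b <- mk_replicate(mk_call(), cell_count = 5L)
  expect_error(mismatch_fraction(a, b), "different cell counts")
})

test_that("noiseless exponential points are recovered to 1e-6", {
  x <- c(1, 2, 5, 25, 50)
  y <- 0.4 * exp(-0.5 * x) + 0.1
  fit <- fit_exponential(x, y)
  expect_lt(abs(fit$a - 0.4), 1e-6)
  expect_lt(abs(fit$b - 0.5), 1e-6)
  expect_lt(abs(fit$c - 0.1), 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("constant points degenerate to a flat curve", {
  fit <- fit_exponential(c(1, 5, 25, 50), rep(0.2, 4))
  expect_lt(fit$a, 1e-4)
  expect_equal(fit$c + fit$a, 0.2, tolerance = 1e-4)
  expect_error(fit_exponential(c(1, 2), c(0.5, 0.3)), "3 points")
})

test_that("decay rate is recovered within 50% under noise (20 seeds)", {
  x <- c(1, 2, 5, 10, 25, 50)
  rel_err <- vapply(1:20, function(sd) {
    set.seed(sd)
    y <- pmax(0.4 * exp(-0.5 * x) + 0.1 + rnorm(length(x), 0, 0.02), 0)
    abs(fit_exponential(x, y)$b - 0.5) / 0.5
  }, numeric(1))
  expect_lt(median(rel_err), 0.5)
})

test_that("genotype-likelihood correlation hits the rank-correlation limits", {
  mk_pl_rep <- function(pls) {
    rows <- lapply(seq_along(pls), function(i)
      mk_call(pos = i * 10L, pl_het = pls[i]))
    mk_replicate(do.call(rbind, rows))
  }
  a <- mk_pl_rep(c(0L, 10L, 20L, 30L, 40L))
  expect_equal(genotype_likelihood_correlation(a, a)$rho, 1)
  b <- mk_pl_rep(c(40L, 30L, 20L, 10L, 0L))
  expect_equal(genotype_likelihood_correlation(a, b)$rho, -1)
  # fewer than 3 shared sites: undefined
  tiny <- mk_pl_rep(c(0L, 10L))
  expect_error(genotype_likelihood_correlation(tiny, tiny), "3 shared")
})

test_that("independent likelihoods decorrelate at large n", {
  set.seed(11)
  pls_a <- sample(0L:200L, 1000, replace = TRUE)
  pls_b <- sample(0L:200L, 1000, replace = TRUE)
  a <- mk_replicate(do.call(rbind, lapply(1:1000, function(i)
    mk_call(pos = i * 3L, pl_het = pls_a[i]))))
  b <- mk_replicate(do.call(rbind, lapply(1:1000, function(i)
    mk_call(pos = i * 3L, pl_het = pls_b[i]))))
  expect_lt(abs(genotype_likelihood_correlation(a, b)$rho), 0.1)
})

test_that("STR comparisons classify dropout, LoH and imbalance", {
  ref <- data.frame(locus = c("A", "B", "C", "D"),
                    het = c(TRUE, TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  obs <- data.frame(locus = c("A", "B", "C", "D"),
                    height1 = c(1000, 0, 1000, 2000),
                    height2 = c(900, 0, 200, 0))
  cmp <- compare_str(ref, obs, imbalance_ratio_threshold = 3)
  st <- as.character(cmp$comparisons$status)
  expect_identical(st, c("concordant", "full_dropout", "partial_dropout",
                         "concordant"))
  expect_identical(cmp$n_affected, 2L)
  # one het peak absent -> complete LoH
  obs2 <- obs; obs2$height2[1] <- 0
  cmp2 <- compare_str(ref, obs2, 3)
  expect_identical(as.character(cmp2$comparisons$status)[1], "complete_loh")
  # balanced everywhere -> nothing affected
  obs3 <- data.frame(locus = ref$locus, height1 = 1000,
                     height2 = c(1000, 1000, 1000, 0))
  expect_identical(compare_str(ref, obs3, 3)$n_affected, 0L)
  # ratio exactly 5 with threshold 3 is partial dropout
  expect_identical(as.character(cmp$comparisons$status)[3], "partial_dropout")
  # panel mismatch rejected
  expect_error(compare_str(ref, obs[1:3, ], 3), "different loci")
})

test_that("variant-set overlap is intersection over reference size", {
  r <- mk_replicate(do.call(rbind, lapply(1:10, function(i)
    mk_call(pos = i * 5L))))
  ref_in <- data.frame(chrom = "chr1", pos = c(5L, 10L, 15L),
                       ref = "A", alt = "G")
  expect_equal(variant_set_overlap(r, ref_in)$overlap_fraction, 1)
  ref_out <- data.frame(chrom = "chr1", pos = c(7L, 8L), ref = "A", alt = "G")
  expect_equal(variant_set_overlap(r, ref_out)$overlap_fraction, 0)
  ref_mix <- data.frame(chrom = "chr1", pos = c(5L, 10L, 15L, 20L, 25L,
                                                7L, 8L, 9L, 11L, 12L),
                        ref = "A", alt = "G")
  res <- variant_set_overlap(r, ref_mix)
  expect_identical(res$intersection, 5L)  # hmm: 5,10,15,20,25 present
  expect_equal(res$overlap_fraction, 0.5)
  expect_error(variant_set_overlap(r, ref_mix[0, ]), "empty reference")
})
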