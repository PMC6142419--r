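# VCF dialect I/O, the standard filters and the per-call transforms.

write_toy_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=chr1,length=1000000>",
              "##contig=<ID=chr2,length=1000000>",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
              "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"p\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1")
  writeLines(c(header, lines), path)
  path
}

test_that("a VCF with biallelic PASS records parses into calls", {
  p <- write_toy_vcf(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD:DP:PL\t0/1:5,5:10:40,0,40",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT:AD:DP:PL\t1/1:0,30:30:500,90,0",
    "chr2\t50\t.\tG\tA\t.\tPASS\t.\tGT:AD:DP:PL\t0/1:20,21:41:70,0,80"))
  r <- read_vcf(p)
  expect_s3_class(r, "assay_replicate")
  expect_identical(nrow(r$calls), 3L)
  expect_identical(r$sample_id, "s1")
  # AD 5,5 gives VAF 0.5 downstream
  expect_equal(suppressWarnings(vaf(r$calls$ad_ref, r$calls$ad_alt))[1], 0.5)
  expect_identical(r$calls$genotype, c("het", "hom_alt", "het"))
})

test_that("multi-allelic and incomplete records are skipped with a warning", {
  p <- write_toy_vcf(c(
    "chr1\t100\t.\tA\tG,T\t.\tPASS\t.\tGT:AD:DP:PL\t1/2:2,5,5:12:90,40,0,50,10,60",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT:AD:DP\t0/1:5,5:10",
    "chr1\t300\t.\tC\tA\t.\tPASS\t.\tGT:AD:DP:PL\t0/1:6,4:10:30,0,50"))
  expect_warning(expect_warning(r <- read_vcf(p), "multi-allelic"), "FORMAT")
  expect_identical(nrow(r$calls), 1L)
  expect_identical(r$calls$pos, 300L)
})

test_that("simulate -> write -> read round-trips exactly", {
  g <- test_genome()
  a <- simulate_assay(g, test_model(), 5L, seed = 77L)
  p <- tempfile(fileext = ".vcf")
  write_vcf(a, p)
  b <- read_vcf(p, cell_count = a$cell_count)
  expect_equal(b$calls, a$calls)
})

test_that("PASS filtering keeps exactly the PASS records in order", {
  r <- mk_replicate(mk_call(pos = 1, filter = "PASS"),
                    mk_call(pos = 2, filter = "q10"),
                    mk_call(pos = 3, filter = "PASS"),
                    mk_call(pos = 4, filter = "LowQual"),
                    mk_call(pos = 5, filter = "q10"))
  f <- filter_pass(r)
  expect_identical(f$calls$pos, c(1L, 3L))
  all_pass <- mk_replicate(mk_call(pos = 1), mk_call(pos = 2))
  expect_identical(filter_pass(all_pass)$calls, all_pass$calls)
  none <- mk_replicate(mk_call(pos = 1, filter = "x"))
  expect_identical(nrow(filter_pass(none)$calls), 0L)
})

test_that("region restriction honors BED half-open semantics", {
  regions <- data.frame(chrom = "chr1", start0 = 0, end1 = 100)
  at100 <- mk_replicate(mk_call(pos = 100))   # 0-based 99: inside [0, 100)
  at101 <- mk_replicate(mk_call(pos = 101))   # 0-based 100: outside
  expect_identical(nrow(restrict_to_regions(at100, regions)$calls), 1L)
  expect_identical(nrow(restrict_to_regions(at101, regions)$calls), 0L)
  # pos 1 with interval [0, 1) is included
  tiny <- data.frame(chrom = "chr1", start0 = 0, end1 = 1)
  expect_identical(nrow(restrict_to_regions(mk_replicate(mk_call(pos = 1)),
                                            tiny)$calls), 1L)
  # calls on chromosomes absent from the region set are dropped
  r <- mk_replicate(mk_call(chrom = "chr9", pos = 5))
  expect_identical(nrow(restrict_to_regions(r, regions)$calls), 0L)
  # enumeration: calls at 10..100, intervals [5,35) and [55,75) keep
  # 0-based 9/19/29 and 59/69 -> 5 calls
  r10 <- mk_replicate(do.call(rbind, lapply(1:10, function(i)
    mk_call(pos = i * 10))))
  reg <- data.frame(chrom = "chr1", start0 = c(5, 55), end1 = c(35, 75))
  expect_identical(nrow(restrict_to_regions(r10, reg)$calls), 5L)
})

test_that("depth filtering is inclusive at the threshold", {
  r <- mk_replicate(mk_call(pos = 1, ad_ref = 15, ad_alt = 15),  # DP 30
                    mk_call(pos = 2, ad_ref = 15, ad_alt = 14),  # DP 29
                    mk_call(pos = 3, ad_ref = 40, ad_alt = 40))
  f <- filter_depth(r, 30)
  expect_identical(f$calls$pos, c(1L, 3L))
  expect_identical(filter_depth(r, 0)$calls, r$calls)  # min_depth 0 = identity
})

test_that("VAF arithmetic and the undefined case", {
  expect_equal(suppressWarnings(vaf(41, 41)), 0.5)
  expect_equal(suppressWarnings(vaf(0, 30)), 1.0)
  expect_equal(suppressWarnings(vaf(3, 1)), 0.25)
  expect_warning(v <- vaf(0, 0), "undefined")
  expect_true(is.na(v))
  expect_error(vaf(-1, 5), "negative")
})

test_that("phred-scaled likelihoods convert to probabilities", {
  expect_equal(pl_to_prob(0), 1.0)
  expect_equal(pl_to_prob(10), 0.1)
  expect_equal(pl_to_prob(30), 0.001)
  expect_error(pl_to_prob(-5), "non-negative")
})

test_that("PASS and depth filters commute and region restriction is idempotent", {
  set.seed(42)
  calls <- do.call(rbind, lapply(1:40, function(i)
    mk_call(chrom = sample(c("chr1", "chr2"), 1), pos = i * 7,
            ad_ref = sample(0:40, 1), ad_alt = sample(1:40, 1),
            filter = sample(c("PASS", "q10"), 1))))
  r <- assay_replicate(calls)
  expect_identical(filter_pass(filter_depth(r, 30))$calls,
                   filter_depth(filter_pass(r), 30)$calls)
  regions <- data.frame(chrom = c("chr1", "chr2"), start0 = c(0, 50),
                        end1 = c(150, 200))
  once <- restrict_to_regions(r, regions)
  twice <- restrict_to_regions(once, regions)
  expect_identical(once$calls, twice$calls)
  # range invariants
  v <- suppressWarnings(vaf(calls$ad_ref, calls$ad_alt))
  expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
  expect_true(all(pl_to_prob(c(0, 1, 10, 100, 1000)) > 0))
  expect_true(all(pl_to_prob(c(0, 1, 10, 100, 1000)) <= 1))
})
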