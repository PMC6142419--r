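# Ground-truth genome for the forward simulator: variant sites, karyotype
# segments and an STR identity panel for a leukemia-like cell line.

#' Describe a copy-number segment in variant-index space
#'
#' Segments are expressed in variant ordinals (the index of a site within its
#' chromosome's site list), not base pairs, because the downstream median
#' filter and window caller operate over variant neighborhoods.
#'
#' @param chrom chromosome label.
#' @param start,end first and last variant index covered (1-based, inclusive).
#' @param state one of `"neutral"`, `"gain"` (3 copies, 2:1 allele ratio),
#'   `"loss"` (1 copy) or `"cn_loh"` (2 copies of one haplotype).
#' @return a one-row `data.frame`.
#' @export
cna_segment <- function(chrom, start, end, state) {
  state <- match.arg(state, c("neutral", "gain", "loss", "cn_loh"))
  if (!is_count(start) || !is_count(end) || start < 1 || end < start)
    abort("invalid segment bounds [%s, %s] on %s", start, end, chrom)
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             state = state, stringsAsFactors = FALSE)
}

#' Default genome specification
#'
#' A scaled-down diploid exome emulating the OCI-AML3 karyotype
#' (48,X,-Y,+1,der(1;7),+5,i(5p),+8,del(13),dup(17q)) plus a copy-neutral LoH
#' on 19q: whole-chromosome trisomies on 5 and 8, a large p-arm loss and a
#' q-arm gain on chromosome 1, a small (< 100 sites) interstitial deletion on
#' 13, a q-arm gain on 17, copy-neutral LoH on 19q, and two fully neutral
#' chromosomes (2 and 3) reserved for noise estimation. Driver mutations are
#' always-heterozygous flagged sites; the NPM1 frameshift is a 4-bp insertion
#' so that indel handling is exercised.
#'
#' @param sites_per_chrom optional named integer vector overriding the number
#'   of variant sites per chromosome.
#' @return a list understood by [build_genome()].
#' @export
default_genome_spec <- function(sites_per_chrom = NULL) {
  chromosomes <- c(chr1 = 700L, chr2 = 400L, chr3 = 400L, chr5 = 400L,
                   chr8 = 600L, chr13 = 500L, chr17 = 400L, chr19 = 500L)
  if (!is.null(sites_per_chrom)) {
    chromosomes[names(sites_per_chrom)] <- as.integer(sites_per_chrom)
  }
  list(
    chromosomes = chromosomes,
    hom_alt_fraction = 0.3,
    coding_length = 2e6,   # sites live in [1, coding_length]
    chrom_length = 1e7,    # false positives may land anywhere in [1, chrom_length]
    cna = rbind(
      cna_segment("chr1", 1L, 320L, "loss"),      # large p-arm loss (del(1p))
      cna_segment("chr1", 451L, 700L, "gain"),    # dup(1q)
      cna_segment("chr5", 1L, 400L, "gain"),      # +5 / i(5p)
      cna_segment("chr8", 1L, 600L, "gain"),      # +8 trisomy
      cna_segment("chr13", 250L, 329L, "loss"),   # small del(13): 80 sites < 100
      cna_segment("chr17", 200L, 400L, "gain"),   # dup(17q)
      cna_segment("chr19", 200L, 500L, "cn_loh")  # del(19q) as copy-neutral LoH
    ),
    drivers = data.frame(
      name  = c("DNMT3A_R882C", "NPM1_W288fs", "NRAS_Q61L"),
      chrom = c("chr2", "chr5", "chr1"),
      index = c(100L, 250L, 350L),   # NRAS sits in the neutral gap of chr1
      ref   = c("C", "T", "A"),
      alt   = c("T", "TCTG", "T"),
      stringsAsFactors = FALSE
    )
  )
}

# PowerPlex-21-style identity panel: 21 loci, 18 heterozygous by default.
default_str_panel <- function(n_het = 18L, seed = 1L) {
  loci <- c("D3S1358", "D1S1656", "D6S1043", "D13S317", "PentaE", "D16S539",
            "D18S51", "D2S1338", "CSF1PO", "PentaD", "TH01", "vWA", "D21S11",
            "D7S820", "D5S818", "TPOX", "D8S1179", "D12S391", "D19S433",
            "FGA", "AMEL")
  set.seed(derive_seed(seed, 77L))
  len1 <- sample(8:30, length(loci), replace = TRUE) * 4L
  het <- rep(FALSE, length(loci))
  het[sample(seq_len(length(loci) - 1L), n_het)] <- TRUE  # AMEL stays hemizygous
  len2 <- ifelse(het, len1 + sample(c(4L, 8L, 12L), length(loci), replace = TRUE), len1)
  data.frame(locus = loci, het = het, len1 = len1, len2 = as.integer(len2),
             stringsAsFactors = FALSE)
}

#' Build a ground-truth genome for simulation
#'
#' Lays out variant sites with strictly increasing positions per chromosome,
#' assigns zygosity (heterozygous or homozygous-alternate) and the haplotype
#' carrying the alternate allele, stamps copy-number segments onto the sites,
#' and derives the post-karyotype truth genotype: heterozygous sites inside a
#' loss or copy-neutral-LoH segment become homozygous for whichever allele
#' rides the retained haplotype.
#'
#' @param spec a specification list as produced by [default_genome_spec()].
#' @param seed integer seed; the genome is deterministic given `(spec, seed)`.
#' @return an object of class `gt_genome`: list with `sites` (data.frame),
#'   `segments`, `str_loci`, and the scalar layout parameters.
#' @export
build_genome <- function(spec = default_genome_spec(), seed = 1L) {
  stopifnot(is.list(spec), all(spec$chromosomes >= 0))
  segs <- spec$cna
  if (is.null(segs)) segs <- cna_segment("chr1", 1L, 1L, "neutral")[0, ]
  # reject overlapping segments, naming the offenders
  if (nrow(segs) > 1) {
    for (ch in unique(segs$chrom)) {
      s <- segs[segs$chrom == ch, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
        i <- which(s$start[-1] <= s$end[-nrow(s)])[1]
        abort("overlapping CNA segments on %s: [%d,%d] and [%d,%d]",
              ch, s$start[i], s$end[i], s$start[i + 1], s$end[i + 1])
      }
    }
  }
  set.seed(derive_seed(seed, 1L))
  bases <- c("A", "C", "G", "T")
  site_list <- lapply(names(spec$chromosomes), function(ch) {
    n <- spec$chromosomes[[ch]]
    if (n == 0L) return(NULL)
    pos <- sort(sample.int(spec$coding_length, n))
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    zyg <- ifelse(stats::runif(n) < spec$hom_alt_fraction, "hom_alt", "het")
    data.frame(chrom = ch, index = seq_len(n), pos = pos, ref = ref, alt = alt,
               zygosity = zyg, alt_hap = sample(1:2, n, replace = TRUE),
               driver = NA_character_, stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_list)
  rownames(sites) <- NULL

  # drivers: always heterozygous, fixed alleles
  drv <- spec$drivers
  if (!is.null(drv) && nrow(drv)) {
    for (i in seq_len(nrow(drv))) {
      j <- which(sites$chrom == drv$chrom[i] & sites$index == drv$index[i])
      if (!length(j)) abort("driver %s addresses a missing site", drv$name[i])
      sites$zygosity[j] <- "het"
      sites$ref[j] <- drv$ref[i]
      sites$alt[j] <- drv$alt[i]
      sites$driver[j] <- drv$name[i]
    }
  }

  # stamp copy states; each segment retains/duplicates one haplotype
  sites$copy_state <- "neutral"
  segs$hap <- if (nrow(segs)) sample(1:2, nrow(segs), replace = TRUE) else integer(0)
  if (nrow(segs)) {
    for (i in seq_len(nrow(segs))) {
      j <- sites$chrom == segs$chrom[i] &
        sites$index >= segs$start[i] & sites$index <= segs$end[i]
      if (!any(j)) next
      sites$copy_state[j] <- segs$state[i]
      sites$seg_hap[j] <- segs$hap[i]
    }
  }
  if (is.null(sites$seg_hap)) sites$seg_hap <- NA_integer_

  # truth genotype after the karyotype is applied
  gt <- ifelse(sites$zygosity == "het", "het", "hom_alt")
  reduced <- sites$copy_state %in% c("loss", "cn_loh") & sites$zygosity == "het"
  gt[reduced] <- ifelse(sites$alt_hap[reduced] == sites$seg_hap[reduced],
                        "hom_alt", "hom_ref")
  # drivers never lose heterozygosity (they sit in neutral segments by design)
  gt[!is.na(sites$driver)] <- "het"
  sites$truth_genotype <- gt

  structure(list(sites = sites, segments = segs,
                 str_loci = default_str_panel(seed = seed),
                 hom_alt_fraction = spec$hom_alt_fraction,
                 coding_length = spec$coding_length,
                 chrom_length = spec$chrom_length,
                 chromosomes = spec$chromosomes, seed = seed),
            class = "gt_genome")
}

#' @export
print.gt_genome <- function(x, ...) {
  cat(sprintf("<gt_genome> %d sites on %d chromosomes; %d CNA segments; %d STR loci (%d het)\n",
              nrow(x$sites), length(x$chromosomes), nrow(x$segments),
              nrow(x$str_loci), sum(x$str_loci$het)))
  invisible(x)
}

#' Coding (target) regions of a simulated genome as BED-style intervals
#'
#' One half-open, 0-based interval per chromosome covering the region in
#' which true variant sites were laid out; simulated amplification-artifact
#' false positives fall mostly outside it.
#'
#' @param genome a `gt_genome`.
#' @return a `data.frame` with `chrom`, `start0`, `end1`.
#' @export
coding_regions <- function(genome) {
  stopifnot(inherits(genome, "gt_genome"))
  data.frame(chrom = names(genome$chromosomes), start0 = 0,
             end1 = genome$coding_length, stringsAsFactors = FALSE)
}
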