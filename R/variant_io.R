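# Reading/writing the single-sample VCF dialect and the per-call filters the
# analyses are built on: PASS status, coding-region restriction, read-depth
# threshold, allele frequency and phred-scaled likelihood transforms.

#' Construct an assay replicate
#'
#' The container for all non-reference calls of one amplified sample. Calls
#' are stored as a data.frame sorted by chromosome then position, keyed by
#' (chrom, pos, ref, alt).
#'
#' @param calls data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `genotype` (`"het"` / `"hom_alt"` / `"hom_ref"`), `ad_ref`, `ad_alt`,
#'   `dp`, `pl_hom_ref`, `pl_het`, `pl_hom_alt`, `filter`.
#' @param sample_id sample label.
#' @param cell_count cells amplified for this assay (NA if unknown).
#' @param replicate_index replicate number within its cell count.
#' @return an object of class `assay_replicate`.
#' @export
assay_replicate <- function(calls, sample_id = "sample",
                            cell_count = NA_integer_, replicate_index = 1L) {
  needed <- c("chrom", "pos", "ref", "alt", "genotype", "ad_ref", "ad_alt",
              "dp", "pl_hom_ref", "pl_het", "pl_hom_alt", "filter")
  missing_cols <- setdiff(needed, names(calls))
  if (length(missing_cols))
    abort("calls is missing columns: %s", paste(missing_cols, collapse = ", "))
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt)
  if (anyDuplicated(key)) abort("duplicate (chrom, pos, ref, alt) keys in calls")
  calls <- calls[, needed, drop = FALSE]  # canonical column order
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  structure(list(sample_id = sample_id,
                 cell_count = as.integer(cell_count),
                 replicate_index = as.integer(replicate_index),
                 calls = calls),
            class = "assay_replicate")
}

#' @export
print.assay_replicate <- function(x, ...) {
  cat(sprintf("<assay_replicate> %s: %d calls (%d het, %d hom_alt), cells=%s\n",
              x$sample_id, nrow(x$calls), sum(x$calls$genotype == "het"),
              sum(x$calls$genotype == "hom_alt"),
              ifelse(is.na(x$cell_count), "?", x$cell_count)))
  invisible(x)
}

n_calls <- function(replicate) nrow(replicate$calls)

replace_calls <- function(replicate, calls) {
  replicate$calls <- calls
  rownames(replicate$calls) <- NULL
  replicate
}

#' Write an assay replicate as a single-sample VCF
#'
#' VCFv4.2 with FORMAT fields GT, AD (ref,alt), DP, PL and one contig header
#' line per chromosome.
#'
#' @param replicate an `assay_replicate`.
#' @param path output file.
#' @param contigs optional named numeric vector of contig lengths; defaults
#'   to the chromosomes present in the calls.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(replicate, path, contigs = NULL) {
  stopifnot(inherits(replicate, "assay_replicate"))
  calls <- replicate$calls
  if (is.null(contigs)) {
    chroms <- unique(calls$chrom)
    contigs <- stats::setNames(rep(3e8, length(chroms)), chroms)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mdaqc",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           replicate$sample_id))
  gt <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")[calls$genotype]
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.\tGT:AD:DP:PL\t%s:%d,%d:%d:%d,%d,%d",
                  calls$chrom, calls$pos, calls$ref, calls$alt, calls$filter,
                  gt, calls$ad_ref, calls$ad_alt, calls$dp,
                  calls$pl_hom_ref, calls$pl_het, calls$pl_hom_alt)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a single-sample VCF into an assay replicate
#'
#' Expects FORMAT fields GT, AD, DP and PL. Multi-allelic records and records
#' with missing required FORMAT values are skipped with a warning (the
#' analyses here are SNV/biallelic by design); homozygous-reference records
#' are dropped.
#'
#' @param path VCF file.
#' @param sample_id,cell_count,replicate_index metadata attached to the
#'   result; `sample_id` defaults to the VCF sample column name.
#' @return an `assay_replicate`.
#' @export
read_vcf <- function(path, sample_id = NULL, cell_count = NA_integer_,
                     replicate_index = 1L) {
  if (!file.exists(path)) abort("no such file: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = list(NULL, colnames(vcfR::getFIX(v))))
  if (ncol(v@gt) < 2) abort("%s: no sample column", path)
  if (is.null(sample_id)) sample_id <- colnames(v@gt)[2]
  n <- nrow(fix)
  if (n == 0)
    return(assay_replicate(empty_calls(), sample_id, cell_count, replicate_index))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    warning(sprintf("%s: skipping %d multi-allelic record(s)", path, sum(multi)))
  gt_m <- vcfR::extract.gt(v, element = "GT")
  ad_m <- vcfR::extract.gt(v, element = "AD")
  dp_m <- vcfR::extract.gt(v, element = "DP")
  pl_m <- vcfR::extract.gt(v, element = "PL")
  bad <- is.na(gt_m[, 1]) | is.na(ad_m[, 1]) | is.na(dp_m[, 1]) | is.na(pl_m[, 1])
  if (any(bad & !multi))
    warning(sprintf("%s: skipping %d record(s) with missing FORMAT fields",
                    path, sum(bad & !multi)))
  keep <- !multi & !bad
  if (!any(keep))
    return(assay_replicate(empty_calls(), sample_id, cell_count, replicate_index))
  ad <- do.call(rbind, strsplit(ad_m[keep, 1], ",", fixed = TRUE))
  pl <- do.call(rbind, strsplit(pl_m[keep, 1], ",", fixed = TRUE))
  if (ncol(pl) < 3) abort("%s: PL does not have 3 components", path)
  gt_raw <- gsub("|", "/", gt_m[keep, 1], fixed = TRUE)
  genotype <- ifelse(gt_raw %in% c("0/1", "1/0"), "het",
                     ifelse(gt_raw == "1/1", "hom_alt", "hom_ref"))
  calls <- data.frame(chrom = fix[keep, "CHROM"],
                      pos = as.integer(fix[keep, "POS"]),
                      ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
                      genotype = genotype,
                      ad_ref = as.integer(ad[, 1]), ad_alt = as.integer(ad[, 2]),
                      dp = as.integer(dp_m[keep, 1]),
                      pl_hom_ref = as.integer(pl[, 1]),
                      pl_het = as.integer(pl[, 2]),
                      pl_hom_alt = as.integer(pl[, 3]),
                      filter = fix[keep, "FILTER"],
                      stringsAsFactors = FALSE)
  calls <- calls[calls$genotype != "hom_ref", , drop = FALSE]
  assay_replicate(calls, sample_id, cell_count, replicate_index)
}

empty_calls <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), genotype = character(0), ad_ref = integer(0),
             ad_alt = integer(0), dp = integer(0), pl_hom_ref = integer(0),
             pl_het = integer(0), pl_hom_alt = integer(0),
             filter = character(0), stringsAsFactors = FALSE)
}

#' Keep only PASS calls
#'
#' @param replicate an `assay_replicate`.
#' @return the filtered replicate (order preserved).
#' @export
filter_pass <- function(replicate) {
  stopifnot(inherits(replicate, "assay_replicate"))
  replace_calls(replicate, replicate$calls[replicate$calls$filter == "PASS", ,
                                           drop = FALSE])
}

#' Keep only calls meeting a read-depth threshold
#'
#' The threshold applies to total depth DP and is inclusive (DP >= min_depth).
#'
#' @param replicate an `assay_replicate`.
#' @param min_depth minimum DP (default 30, the analyses' standard cutoff).
#' @return the filtered replicate.
#' @export
filter_depth <- function(replicate, min_depth = 30) {
  stopifnot(inherits(replicate, "assay_replicate"), min_depth >= 0)
  replace_calls(replicate, replicate$calls[replicate$calls$dp >= min_depth, ,
                                           drop = FALSE])
}

#' Read a 3-column BED file of target regions
#'
#' @param path BED file (chrom, start, end; 0-based half-open).
#' @return a `data.frame` with `chrom`, `start0`, `end1`, sorted and merged
#'   per chromosome.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort("no such file: %s", path)
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)[, 1:3]
  names(bed) <- c("chrom", "start0", "end1")
  merge_regions(bed)
}

# sort and merge overlapping/adjacent half-open intervals per chromosome
merge_regions <- function(regions) {
  stopifnot(all(c("chrom", "start0", "end1") %in% names(regions)))
  if (any(regions$end1 < regions$start0)) abort("BED interval with end < start")
  out <- lapply(split(regions, regions$chrom), function(r) {
    r <- r[order(r$start0, r$end1), , drop = FALSE]
    keep_start <- r$start0
    keep_end <- r$end1
    j <- 1L
    for (i in seq_len(nrow(r))[-1]) {
      if (r$start0[i] <= keep_end[j]) {
        keep_end[j] <- max(keep_end[j], r$end1[i])
      } else {
        j <- j + 1L
        keep_start[j] <- r$start0[i]; keep_end[j] <- r$end1[i]
      }
    }
    data.frame(chrom = r$chrom[1], start0 = keep_start[1:j], end1 = keep_end[1:j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Restrict calls to target regions
#'
#' A call at 1-based position `pos` is retained when `pos - 1` falls inside a
#' half-open `[start0, end1)` interval of its chromosome. Calls on
#' chromosomes absent from the region set are dropped.
#'
#' @param replicate an `assay_replicate`.
#' @param regions a region `data.frame` as from [read_bed()] or
#'   [coding_regions()].
#' @return the filtered replicate.
#' @export
restrict_to_regions <- function(replicate, regions) {
  stopifnot(inherits(replicate, "assay_replicate"))
  regions <- merge_regions(regions)
  calls <- replicate$calls
  inside <- logical(nrow(calls))
  for (ch in unique(calls$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    i <- which(calls$chrom == ch)
    if (!nrow(r)) next
    p0 <- calls$pos[i] - 1L  # VCF 1-based -> BED 0-based
    hit <- rep(FALSE, length(i))
    for (j in seq_len(nrow(r)))
      hit <- hit | (p0 >= r$start0[j] & p0 < r$end1[j])
    inside[i] <- hit
  }
  replace_calls(replicate, calls[inside, , drop = FALSE])
}

#' Variant allele frequency from allelic depths
#'
#' @param ad_ref,ad_alt reference and alternate allelic depths (vectorized).
#' @return `ad_alt / (ad_ref + ad_alt)`; `NA` (with a warning) where the
#'   allelic depth sum is zero, where the frequency is undefined.
#' @export
vaf <- function(ad_ref, ad_alt) {
  stopifnot(length(ad_ref) == length(ad_alt))
  if (any(ad_ref < 0 | ad_alt < 0, na.rm = TRUE)) abort("negative allelic depth")
  tot <- ad_ref + ad_alt
  if (any(tot == 0, na.rm = TRUE))
    warning("VAF undefined at sites with zero allelic depth; returning NA")
  ifelse(tot > 0, ad_alt / tot, NA_real_)
}

# VAF column for a replicate's calls
call_vaf <- function(replicate) {
  suppressWarnings(vaf(replicate$calls$ad_ref, replicate$calls$ad_alt))
}

#' Convert a phred-scaled likelihood to a probability
#'
#' P = 10^(-PL / 10): PL 0 is probability 1, PL 10 is 0.1.
#'
#' @param pl non-negative phred-scaled likelihood value(s).
#' @return probabilities in (0, 1].
#' @export
pl_to_prob <- function(pl) {
  if (any(pl < 0, na.rm = TRUE)) abort("PL values must be non-negative")
  10^(-pl / 10)
}

# TRUE where ref/alt describe a single-nucleotide variant
is_snv <- function(ref, alt) nchar(ref) == 1L & nchar(alt) == 1L
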