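# Forward simulation of sparse-cell MDA + exome sequencing.
#
# Per site and haplotype, each input cell contributes one template molecule
# per haplotype copy. A template seeds amplification with probability
# `template_survival`; surviving templates draw independent Gamma-distributed
# amplification gains (heavy-tailed for small shape), so the pooled
# alternate-allele fraction of the amplicon mass is
#   f = sum(alt gains) / sum(all gains).
# Since a sum of m iid Gamma(k) draws is Gamma(m * k), the pooled gain per
# allele is drawn in one Gamma call. Sequencing reads are then a negative
# binomial depth and a binomial thinning of f (with a symmetric per-read
# miscall probability), and genotype likelihoods are the three diploid
# binomial likelihoods, phred-scaled and normalized so the best genotype has
# PL 0 (the standard GATK convention).

#' Amplification and sequencing noise model
#'
#' Defaults are the package's calibrated study conditions: they put the
#' single-cell replicate allelic mismatch in the 0.3-0.5 range and at least
#' double the heterozygous-allele-frequency SNR from 1 to 50 cells (see the
#' methods vignette for the calibration).
#'
#' @param template_survival probability in (0, 1] that a template molecule
#'   seeds amplification.
#' @param gain_shape shape of the per-template Gamma amplification gain;
#'   small values give heavy-tailed allelic imbalance.
#' @param sequencing_error per-read miscall probability.
#' @param mean_depth target mean coverage per site.
#' @param depth_dispersion negative-binomial size parameter of the depth
#'   model (smaller = more overdispersed).
#' @param fp_rate expected number of amplification-artifact false-positive
#'   variants per assay at single-cell input; scales as 1/cell_count. Most
#'   artifact sites fall outside the coding target regions.
#' @return an object of class `amp_model`.
#' @export
amplification_model <- function(template_survival = 0.9,
                                gain_shape = 1.0,
                                sequencing_error = 0.002,
                                mean_depth = 90,
                                depth_dispersion = 3.0,
                                fp_rate = 0) {
  stopifnot(template_survival > 0, template_survival <= 1,
            sequencing_error >= 0, sequencing_error <= 1,
            gain_shape > 0, mean_depth > 0, depth_dispersion > 0, fp_rate >= 0)
  structure(list(template_survival = template_survival, gain_shape = gain_shape,
                 sequencing_error = sequencing_error, mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion, fp_rate = fp_rate),
            class = "amp_model")
}

#' Simulation configuration
#'
#' @param cell_counts integer vector of cell inputs (the study's dilution
#'   series by default).
#' @param replicates_per_count replicates per cell count; concordance
#'   analyses need at least 2.
#' @param seed top-level integer seed.
#' @param genome a `gt_genome` (built from [default_genome_spec()] if omitted).
#' @param model an `amp_model`.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(cell_counts = c(1L, 2L, 5L, 10L, 25L, 50L),
                              replicates_per_count = 2L,
                              seed = 1L,
                              genome = NULL,
                              model = amplification_model()) {
  stopifnot(all(cell_counts >= 1), replicates_per_count >= 1)
  if (is.null(genome)) genome <- build_genome(seed = seed)
  structure(list(cell_counts = as.integer(cell_counts),
                 replicates_per_count = as.integer(replicates_per_count),
                 seed = as.integer(seed), genome = genome, model = model),
            class = "sim_config")
}

# per-cell allele copy numbers implied by zygosity + copy state
allele_copies <- function(sites) {
  c_alt <- integer(nrow(sites))
  c_ref <- integer(nrow(sites))
  het <- sites$zygosity == "het"
  st <- sites$copy_state
  on_seg <- sites$alt_hap == sites$seg_hap  # alt rides the affected haplotype
  c_alt[het] <- 1L; c_ref[het] <- 1L
  c_alt[!het] <- 2L
  gain <- st == "gain"
  c_alt[gain & het & on_seg] <- 2L
  c_ref[gain & het & !on_seg] <- 2L
  c_alt[gain & !het] <- 3L
  loss <- st == "loss"
  c_alt[loss & het] <- ifelse(on_seg[loss & het], 1L, 0L)
  c_ref[loss & het] <- ifelse(on_seg[loss & het], 0L, 1L)
  c_alt[loss & !het] <- 1L
  loh <- st == "cn_loh"
  c_alt[loh & het] <- ifelse(on_seg[loh & het], 2L, 0L)
  c_ref[loh & het] <- ifelse(on_seg[loh & het], 0L, 2L)
  list(alt = c_alt, ref = c_ref)
}

# phred-scaled genotype likelihoods from allelic read counts
genotype_pl <- function(alt_reads, dp, err) {
  p_geno <- c(err, 0.5, 1 - err)  # expected alt fraction for 0/0, 0/1, 1/1
  ll <- vapply(p_geno, function(p) stats::dbinom(alt_reads, dp, p, log = TRUE),
               numeric(length(alt_reads)))
  ll <- matrix(ll, ncol = 3L)
  pl <- round(-10 * ll / log(10))
  pl <- pl - apply(pl, 1L, min)
  pl[pl > 99999] <- 99999
  pl
}

#' Simulate one whole-genome-amplified sequencing assay
#'
#' @param genome a `gt_genome`.
#' @param model an `amp_model`.
#' @param cell_count number of input cells (>= 1).
#' @param seed integer seed; the assay is deterministic given its arguments.
#' @param replicate_index replicate label stored on the result.
#' @return an `assay_replicate` (see [assay_replicate()]): all non-reference
#'   calls with GT/AD/DP/PL. Sites whose templates all fail, that draw zero
#'   depth, or that are called homozygous-reference are omitted, mirroring
#'   single-sample VCF output.
#' @export
simulate_assay <- function(genome, model, cell_count, seed,
                           replicate_index = 1L) {
  stopifnot(inherits(genome, "gt_genome"), inherits(model, "amp_model"))
  if (!is_count(cell_count) || cell_count < 1)
    abort("cell_count must be a positive integer, got %s", format(cell_count))
  set.seed(seed)
  s <- genome$sites
  n <- nrow(s)
  cp <- allele_copies(s)
  k <- model$gain_shape
  # templates entering amplification, then survival thinning
  ns_alt <- stats::rbinom(n, cp$alt * cell_count, model$template_survival)
  ns_ref <- stats::rbinom(n, cp$ref * cell_count, model$template_survival)
  # pooled Gamma gains: sum of m iid Gamma(k) == Gamma(m*k); shape 0 -> mass 0
  g_alt <- stats::rgamma(n, shape = ns_alt * k)
  g_ref <- stats::rgamma(n, shape = ns_ref * k)
  tot <- g_alt + g_ref
  f <- ifelse(tot > 0, g_alt / tot, NA_real_)
  dp <- stats::rnbinom(n, size = model$depth_dispersion, mu = model$mean_depth)
  e <- model$sequencing_error
  p_alt <- f * (1 - e) + (1 - f) * e
  alt_reads <- suppressWarnings(stats::rbinom(n, dp, p_alt))
  keep <- !is.na(f) & dp > 0

  calls <- data.frame(chrom = s$chrom[keep], pos = s$pos[keep],
                      ref = s$ref[keep], alt = s$alt[keep],
                      dp = dp[keep], ad_alt = alt_reads[keep],
                      stringsAsFactors = FALSE)
  calls$ad_ref <- calls$dp - calls$ad_alt
  pl <- genotype_pl(calls$ad_alt, calls$dp, max(e, 1e-4))
  calls$genotype <- c("hom_ref", "het", "hom_alt")[max.col(-pl, ties.method = "last")]
  calls$pl_hom_ref <- pl[, 1L]; calls$pl_het <- pl[, 2L]; calls$pl_hom_alt <- pl[, 3L]
  calls$filter <- "PASS"
  calls <- calls[calls$genotype != "hom_ref", , drop = FALSE]

  # amplification-artifact false positives, mostly off-target, 1/cells scaling
  if (model$fp_rate > 0) {
    n_fp <- stats::rpois(1L, model$fp_rate / cell_count)
    if (n_fp > 0) {
      bases <- c("A", "C", "G", "T")
      fp_chrom <- sample(names(genome$chromosomes), n_fp, replace = TRUE)
      fp_pos <- sample.int(genome$chrom_length, n_fp)
      fp_ref <- sample(bases, n_fp, replace = TRUE)
      fp_alt <- vapply(fp_ref, function(r) sample(setdiff(bases, r), 1L), "")
      fp_f <- stats::rbeta(n_fp, 0.8, 1.6)
      fp_dp <- stats::rnbinom(n_fp, size = model$depth_dispersion,
                              mu = model$mean_depth)
      fp_alt_reads <- suppressWarnings(stats::rbinom(n_fp, fp_dp, fp_f))
      ok <- fp_dp > 0 & fp_alt_reads > 0
      if (any(ok)) {
        fp <- data.frame(chrom = fp_chrom[ok], pos = fp_pos[ok],
                         ref = fp_ref[ok], alt = fp_alt[ok], dp = fp_dp[ok],
                         ad_alt = fp_alt_reads[ok], stringsAsFactors = FALSE)
        fp$ad_ref <- fp$dp - fp$ad_alt
        plf <- genotype_pl(fp$ad_alt, fp$dp, max(e, 1e-4))
        fp$genotype <- c("hom_ref", "het", "hom_alt")[max.col(-plf, ties.method = "last")]
        fp$pl_hom_ref <- plf[, 1L]; fp$pl_het <- plf[, 2L]; fp$pl_hom_alt <- plf[, 3L]
        fp$filter <- "PASS"
        fp <- fp[fp$genotype != "hom_ref", , drop = FALSE]
        # true sites win on position collision (vanishingly rare)
        key <- paste(calls$chrom, calls$pos)
        fp <- fp[!(paste(fp$chrom, fp$pos) %in% key), , drop = FALSE]
        calls <- rbind(calls, fp)
      }
    }
  }
  calls <- calls[order(match(calls$chrom, names(genome$chromosomes)), calls$pos), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  assay_replicate(calls,
                  sample_id = sprintf("cells%d_rep%d", cell_count, replicate_index),
                  cell_count = cell_count, replicate_index = replicate_index)
}

#' Simulate an STR identity-panel run
#'
#' Peak heights arise from the same template-survival / Gamma-gain mechanism
#' as the sequencing simulator: a haplotype whose templates all fail yields a
#' peak height of 0 (allele dropout); surviving haplotypes get heights
#' proportional to their pooled amplification gain. Homozygous loci carry a
#' single peak (height in `height1`, `height2 = 0` by convention).
#'
#' @inheritParams simulate_assay
#' @return a `data.frame` with `locus`, `len1`, `len2`, `height1`, `height2`.
#' @export
simulate_str_panel <- function(genome, model, cell_count, seed) {
  stopifnot(inherits(genome, "gt_genome"))
  if (!is_count(cell_count) || cell_count < 1)
    abort("cell_count must be a positive integer, got %s", format(cell_count))
  panel <- genome$str_loci
  set.seed(derive_seed(seed, 3L))
  k <- model$gain_shape
  nloc <- nrow(panel)
  # haplotype template counts: het loci split 1/1 per cell, hom pool both
  n1 <- ifelse(panel$het, cell_count, 2L * cell_count)
  n2 <- ifelse(panel$het, cell_count, 0L)
  ns1 <- stats::rbinom(nloc, n1, model$template_survival)
  ns2 <- stats::rbinom(nloc, n2, model$template_survival)
  g1 <- stats::rgamma(nloc, shape = ns1 * k)
  g2 <- stats::rgamma(nloc, shape = ns2 * k)
  scale <- 2000 / (cell_count * k * model$template_survival)
  data.frame(locus = panel$locus, len1 = panel$len1, len2 = panel$len2,
             height1 = round(g1 * scale), height2 = round(g2 * scale),
             stringsAsFactors = FALSE)
}

#' Simulate a full dilution series in memory
#'
#' @param config a `sim_config`.
#' @return a list with `replicates` (list of `assay_replicate`), `str`
#'   (long data.frame of STR runs keyed by cell count and replicate),
#'   `str_reference` (the balanced bulk panel), and `genome`.
#' @export
simulate_fixture_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- config$genome
  reps <- list()
  strs <- list()
  idx <- 0L
  for (cc in config$cell_counts) {
    for (r in seq_len(config$replicates_per_count)) {
      idx <- idx + 1L
      sd_a <- derive_seed(config$seed, idx)
      rep_obj <- simulate_assay(genome, config$model, cc, sd_a, replicate_index = r)
      reps[[rep_obj$sample_id]] <- rep_obj
      st <- simulate_str_panel(genome, config$model, cc, sd_a)
      st$cell_count <- cc; st$replicate <- r
      strs[[length(strs) + 1L]] <- st
    }
  }
  ref <- genome$str_loci
  bulk <- data.frame(locus = ref$locus, het = ref$het,
                     len1 = ref$len1, len2 = ref$len2,
                     height1 = ifelse(ref$het, 2000, 4000),
                     height2 = ifelse(ref$het, 2000, 0),
                     stringsAsFactors = FALSE)
  list(replicates = reps, str = do.call(rbind, strs), str_reference = bulk,
       genome = genome)
}

#' Write a simulated fixture set to disk
#'
#' Emits one single-sample VCF per (cell count, replicate), the STR panel
#' table, the coding-region BED, a tab-separated truth sidecar (per-site
#' truth genotype and copy state) for parameter-recovery tests, and a JSON
#' manifest describing the samples.
#'
#' @param config a `sim_config`.
#' @param out_dir destination directory (created if needed).
#' @return invisibly, the manifest as a list.
#' @export
write_fixture_set <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort("cannot create output directory %s", out_dir)
  fx <- simulate_fixture_set(config)
  samples <- data.frame(path = character(0), cell_count = integer(0),
                        replicate = integer(0), stringsAsFactors = FALSE)
  for (rep_obj in fx$replicates) {
    path <- file.path(out_dir, paste0(rep_obj$sample_id, ".vcf"))
    write_vcf(rep_obj, path, contigs = stats::setNames(
      rep(config$genome$chrom_length, length(config$genome$chromosomes)),
      names(config$genome$chromosomes)))
    samples <- rbind(samples, data.frame(
      path = basename(path), cell_count = rep_obj$cell_count,
      replicate = rep_obj$replicate_index, stringsAsFactors = FALSE))
  }
  utils::write.table(fx$str, file.path(out_dir, "str_panel.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(fx$str_reference, file.path(out_dir, "str_reference.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  truth <- fx$genome$sites[, c("chrom", "pos", "ref", "alt",
                               "truth_genotype", "copy_state", "driver")]
  utils::write.table(truth, file.path(out_dir, "truth_sites.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  bed <- coding_regions(fx$genome)
  utils::write.table(bed, file.path(out_dir, "coding.bed"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  manifest <- list(seed = config$seed,
                   cell_counts = config$cell_counts,
                   replicates_per_count = config$replicates_per_count,
                   model = unclass(config$model),
                   samples = samples)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
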