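# Replicate concordance: per-site mismatch classification, the mismatch-vs-
# cell-input curve with constrained exponential fit, genotype-likelihood
# correlation, STR dropout scoring and variant-set overlap.

PAIR_CLASSES <- c("concordant", "loh", "allele_change", "total_dropout")

#' Classify one site compared across two replicates
#'
#' Mismatch classes follow the replicate-reproducibility definition: loss of
#' heterozygosity (het in one replicate, homozygous-alt in the other), change
#' of the variant allele, or total dropout (called in only one replicate).
#'
#' @param call_a,call_b one-row call data.frames (columns `alt`, `genotype`)
#'   or `NULL` when the site is absent from that replicate.
#' @return one of `"concordant"`, `"loh"`, `"allele_change"`,
#'   `"total_dropout"`.
#' @export
classify_site_pair <- function(call_a, call_b) {
  a_absent <- is.null(call_a) || nrow(call_a) == 0
  b_absent <- is.null(call_b) || nrow(call_b) == 0
  if (a_absent && b_absent)
    abort("site absent from both replicates is not in the comparison universe")
  if (a_absent || b_absent) return("total_dropout")
  if (call_a$alt != call_b$alt) return("allele_change")
  if (call_a$genotype == call_b$genotype) return("concordant")
  "loh"
}

# vectorized pair classification over the union of non-reference sites
pair_site_table <- function(rep_a, rep_b, snvs_only = TRUE) {
  a <- rep_a$calls[, c("chrom", "pos", "ref", "alt", "genotype")]
  b <- rep_b$calls[, c("chrom", "pos", "ref", "alt", "genotype")]
  if (snvs_only) {
    a <- a[is_snv(a$ref, a$alt), , drop = FALSE]
    b <- b[is_snv(b$ref, b$alt), , drop = FALSE]
  }
  m <- merge(a, b, by = c("chrom", "pos"), all = TRUE,
             suffixes = c("_a", "_b"))
  cls <- character(nrow(m))
  absent_a <- is.na(m$genotype_a)
  absent_b <- is.na(m$genotype_b)
  cls[absent_a | absent_b] <- "total_dropout"
  both <- !absent_a & !absent_b
  cls[both & m$alt_a != m$alt_b] <- "allele_change"
  same <- both & m$alt_a == m$alt_b
  cls[same & m$genotype_a == m$genotype_b] <- "concordant"
  cls[same & m$genotype_a != m$genotype_b] <- "loh"
  m$class <- cls
  m
}

#' Allelic mismatch between two replicate assays
#'
#' The comparison universe is the union of non-reference sites of both
#' replicates (keyed by chromosome and position). The mismatch fraction is
#' the share of the universe classified loh, allele_change or total_dropout.
#' Indels are excluded by default so the statistic is an SNV mismatch.
#'
#' @param rep_a,rep_b `assay_replicate`s with the same cell count.
#' @param snvs_only drop indel calls before comparing (default `TRUE`).
#' @return an object of class `mismatch_summary`: cell count, universe size,
#'   per-class counts, the union mismatch fraction and the two directional
#'   fractions (share of each replicate's own calls not concordantly
#'   reproduced in the other).
#' @export
mismatch_fraction <- function(rep_a, rep_b, snvs_only = TRUE) {
  stopifnot(inherits(rep_a, "assay_replicate"), inherits(rep_b, "assay_replicate"))
  if (!is.na(rep_a$cell_count) && !is.na(rep_b$cell_count) &&
      rep_a$cell_count != rep_b$cell_count)
    abort("replicates have different cell counts (%d vs %d)",
          rep_a$cell_count, rep_b$cell_count)
  m <- pair_site_table(rep_a, rep_b, snvs_only = snvs_only)
  n <- nrow(m)
  if (n == 0) abort("empty comparison universe: no non-reference sites")
  counts <- table(factor(m$class, levels = PAIR_CLASSES))
  frac <- unname(sum(counts[c("loh", "allele_change", "total_dropout")]) / n)
  in_a <- !is.na(m$genotype_a)
  in_b <- !is.na(m$genotype_b)
  structure(list(cell_count = rep_a$cell_count,
                 n_sites = n,
                 counts = as.list(as.integer(counts)) |>
                   stats::setNames(PAIR_CLASSES),
                 mismatch_fraction = frac,
                 directional_a = unname(sum(m$class[in_a] != "concordant") / sum(in_a)),
                 directional_b = unname(sum(m$class[in_b] != "concordant") / sum(in_b))),
            class = "mismatch_summary")
}

#' @export
print.mismatch_summary <- function(x, ...) {
  cat(sprintf("<mismatch_summary> cells=%s n=%d mismatch=%.3f (loh=%d change=%d dropout=%d)\n",
              ifelse(is.na(x$cell_count), "?", x$cell_count), x$n_sites,
              x$mismatch_fraction, x$counts$loh, x$counts$allele_change,
              x$counts$total_dropout))
  invisible(x)
}

#' Mismatch fraction as a function of cell input
#'
#' @param summaries list of `mismatch_summary` objects (several per cell
#'   count allowed; ties are averaged).
#' @return a `data.frame` with one row per cell count: `cell_count`,
#'   `mismatch` (mean fraction), `n_pairs`.
#' @export
mismatch_curve <- function(summaries) {
  stopifnot(length(summaries) >= 1,
            all(vapply(summaries, inherits, TRUE, "mismatch_summary")))
  cc <- vapply(summaries, function(s) as.numeric(s$cell_count), 0)
  fr <- vapply(summaries, function(s) s$mismatch_fraction, 0)
  agg <- stats::aggregate(fr, by = list(cell_count = cc), FUN = mean)
  cnt <- stats::aggregate(fr, by = list(cell_count = cc), FUN = length)
  out <- data.frame(cell_count = agg$cell_count, mismatch = agg$x,
                    n_pairs = cnt$x)
  out[order(out$cell_count), , drop = FALSE]
}

#' Fit a decaying exponential with a floor to curve points
#'
#' Least-squares fit of `y = a * exp(-b * x) + c` with `a, b, c >= 0`
#' (Levenberg-Marquardt with box constraints, multi-start over decay rates).
#' The floor `c` accommodates the nonzero mismatch plateau at high cell
#' input.
#'
#' @param x,y numeric vectors (>= 3 points), e.g. cell counts and mismatch
#'   fractions.
#' @return an object of class `exp_fit`: `a`, `b`, `c`, `rss`, `r_squared`,
#'   `fitted` (function of x), `converged`.
#' @export
fit_exponential <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) abort("need at least 3 points to fit an exponential")
  dat <- data.frame(x = x, y = y)
  best <- NULL
  starts <- list()
  if (stats::sd(y) > .Machine$double.eps^0.5) {
    c0 <- max(min(y) * 0.9, 0)
    a0 <- max(max(y) - c0, 1e-6)
    pos <- y - c0 > 1e-12
    if (sum(pos) >= 2) {
      sl <- stats::coef(stats::lm(log(y[pos] - c0 + 1e-12) ~ x[pos]))[2]
      if (is.finite(sl) && sl < 0) starts <- list(c(a = a0, b = -sl, c = c0))
    }
  }
  for (b0 in 10^seq(-3, 1, length.out = 9))
    starts[[length(starts) + 1L]] <- c(a = max(max(y) - min(y), 1e-6),
                                       b = b0, c = max(min(y), 0))
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-b * x) + c, data = dat, start = as.list(st),
                        lower = c(a = 0, b = 0, c = 0),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = stats::coef(fit), rss = rss)
  }
  if (is.null(best)) {
    # degenerate data (e.g. constant y): flat curve is the least-squares answer
    best <- list(par = c(a = 0, b = 0, c = mean(y)),
                 rss = sum((y - mean(y))^2))
    converged <- FALSE
  } else converged <- TRUE
  p <- best$par
  tss <- sum((y - mean(y))^2)
  structure(list(a = unname(p["a"]), b = unname(p["b"]), c = unname(p["c"]),
                 rss = best$rss,
                 r_squared = if (tss > 0) 1 - best$rss / tss else NA_real_,
                 fitted = function(x) p["a"] * exp(-p["b"] * x) + p["c"],
                 converged = converged),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> y = %.4g * exp(-%.4g x) + %.4g (rss=%.3g, R2=%.3f)\n",
              x$a, x$b, x$c, x$rss, x$r_squared))
  invisible(x)
}

#' Spearman correlation of heterozygous-genotype likelihoods
#'
#' For sites shared by the two replicates, transforms each side's
#' heterozygous PL component into a probability (P = 10^(-PL/10)) and
#' returns the Spearman rank correlation (average ranks for ties).
#'
#' @param rep_a,rep_b `assay_replicate`s.
#' @param snvs_only restrict to SNVs (default `TRUE`).
#' @return list with `rho`, `n_shared`.
#' @export
genotype_likelihood_correlation <- function(rep_a, rep_b, snvs_only = TRUE) {
  m <- pair_site_table(rep_a, rep_b, snvs_only = snvs_only)
  shared <- m[m$class %in% c("concordant", "loh"), , drop = FALSE]
  key_a <- paste(rep_a$calls$chrom, rep_a$calls$pos)
  key_b <- paste(rep_b$calls$chrom, rep_b$calls$pos)
  ks <- paste(shared$chrom, shared$pos)
  pa <- pl_to_prob(rep_a$calls$pl_het[match(ks, key_a)])
  pb <- pl_to_prob(rep_b$calls$pl_het[match(ks, key_b)])
  if (length(pa) < 3)
    abort("fewer than 3 shared sites; genotype-likelihood correlation undefined")
  list(rho = stats::cor(pa, pb, method = "spearman"), n_shared = length(pa))
}

STR_CLASSES <- c("concordant", "full_dropout", "complete_loh", "partial_dropout")

#' Score an STR panel run against its reference genotype
#'
#' Per locus: `full_dropout` when every expected peak is absent,
#' `complete_loh` when exactly one of a heterozygous locus' two peaks is
#' absent, `partial_dropout` when both peaks are present but their height
#' ratio exceeds the imbalance threshold. Only loci heterozygous in the
#' reference are eligible for `complete_loh` / `partial_dropout`.
#'
#' @param reference panel data.frame with `locus`, `het`, and peak heights of
#'   the bulk genotype.
#' @param observed simulated/measured panel (`locus`, `height1`, `height2`).
#' @param imbalance_ratio_threshold peak-height ratio beyond which a
#'   heterozygous locus counts as partial dropout (default 3).
#' @return list with `comparisons` (per-locus data.frame) and
#'   `n_affected` (loci in any non-concordant class).
#' @export
compare_str <- function(reference, observed, imbalance_ratio_threshold = 3) {
  stopifnot(imbalance_ratio_threshold > 0)
  if (!setequal(reference$locus, observed$locus) ||
      nrow(reference) != nrow(observed))
    abort("reference and observed STR panels cover different loci")
  observed <- observed[match(reference$locus, observed$locus), , drop = FALSE]
  het <- as.logical(reference$het)
  h1 <- observed$height1
  h2 <- observed$height2
  status <- rep("concordant", nrow(reference))
  ratio <- ifelse(het & h1 > 0 & h2 > 0, pmax(h1, h2) / pmin(h1, h2), NA_real_)
  status[het & h1 > 0 & h2 > 0 & ratio > imbalance_ratio_threshold] <- "partial_dropout"
  status[het & xor(h1 == 0, h2 == 0)] <- "complete_loh"
  status[het & h1 == 0 & h2 == 0] <- "full_dropout"
  status[!het & h1 == 0] <- "full_dropout"
  comparisons <- data.frame(locus = reference$locus, het = het,
                            height1 = h1, height2 = h2, ratio = ratio,
                            status = factor(status, levels = STR_CLASSES),
                            stringsAsFactors = FALSE)
  list(comparisons = comparisons,
       n_affected = sum(status != "concordant"))
}

#' Overlap between a replicate's variants and a reference variant list
#'
#' @param replicate an `assay_replicate`.
#' @param reference data.frame with `chrom`, `pos`, `ref`, `alt` (e.g. a
#'   published somatic-variant list).
#' @return list with `replicate_id`, `reference_size`, `intersection`,
#'   `overlap_fraction` (intersection over reference size).
#' @export
variant_set_overlap <- function(replicate, reference) {
  stopifnot(inherits(replicate, "assay_replicate"))
  if (is.null(reference) || nrow(reference) == 0)
    abort("empty reference variant list; overlap undefined")
  key_rep <- paste(replicate$calls$chrom, replicate$calls$pos,
                   replicate$calls$ref, replicate$calls$alt)
  key_ref <- paste(reference$chrom, reference$pos, reference$ref, reference$alt)
  inter <- sum(unique(key_ref) %in% key_rep)
  list(replicate_id = replicate$sample_id,
       reference_size = length(unique(key_ref)),
       intersection = inter,
       overlap_fraction = inter / length(unique(key_ref)))
}
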