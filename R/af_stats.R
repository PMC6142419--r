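# Signal-to-noise of heterozygous allele frequencies: the mean het VAF (the
# "signal", ~0.5 on a copy-neutral chromosome) over its standard deviation
# (the amplification "noise"); the reciprocal is the coefficient of
# variation. Computed on user-designated CNA-free chromosomes so copy states
# do not inflate the dispersion.

#' Heterozygous allele frequencies from selected chromosomes
#'
#' @param replicate an `assay_replicate`.
#' @param chromosomes chromosome labels to use (default `chr2`/`chr3`, the
#'   copy-neutral pair of the default simulated genome).
#' @param min_depth inclusive DP threshold (default 30).
#' @return numeric vector of VAFs of heterozygous calls, in positional order.
#' @export
het_af_values <- function(replicate, chromosomes = c("chr2", "chr3"),
                          min_depth = 30) {
  stopifnot(inherits(replicate, "assay_replicate"))
  r <- filter_depth(replicate, min_depth)
  calls <- r$calls
  keep <- calls$genotype == "het" & calls$chrom %in% chromosomes
  calls <- calls[keep, , drop = FALSE]
  calls <- calls[order(match(calls$chrom, chromosomes), calls$pos), , drop = FALSE]
  suppressWarnings(vaf(calls$ad_ref, calls$ad_alt))
}

#' Signal-to-noise ratio of allele frequencies
#'
#' SNR = mu / sigma with sigma the sample (n-1) standard deviation; the
#' coefficient of variation CV = sigma / mu is its reciprocal.
#'
#' @param values numeric VAF vector, length >= 2.
#' @return object of class `het_af_stats`: `n`, `mu`, `sigma`, `snr`, `cv`.
#'   When `sigma` is 0 the SNR is undefined and returned as `NA` with a
#'   warning.
#' @export
compute_snr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) abort("need at least 2 values to estimate dispersion")
  mu <- mean(values)
  sigma <- stats::sd(values)
  if (sigma == 0) {
    warning("zero dispersion: SNR undefined")
    snr <- NA_real_; cv <- NA_real_
  } else {
    snr <- mu / sigma
    cv <- sigma / mu
  }
  structure(list(n = length(values), mu = mu, sigma = sigma, snr = snr, cv = cv),
            class = "het_af_stats")
}

#' @export
print.het_af_stats <- function(x, ...) {
  cat(sprintf("<het_af_stats> n=%d mu=%.4f sigma=%.4f SNR=%.2f CV=%.3f\n",
              x$n, x$mu, x$sigma, x$snr, x$cv))
  invisible(x)
}

#' Anderson-Darling normality check of allele frequencies
#'
#' Composite Anderson-Darling test (mean and variance estimated from the
#' data, via \code{nortest::ad.test}); the distribution "passes" when the
#' test does not reject normality at `alpha`.
#'
#' @param values numeric vector, n >= 8.
#' @param alpha significance level (default 0.05).
#' @return list with `statistic`, `p_value`, `pass`.
#' @export
test_normality <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 8) abort("need at least 8 values for the normality test")
  if (stats::sd(values) == 0) abort("degenerate (constant) sample")
  t <- nortest::ad.test(values)
  list(statistic = unname(t$statistic), p_value = unname(t$p.value),
       pass = unname(t$p.value) > alpha)
}

#' SNR as a function of cell input
#'
#' Ordinary least squares of SNR against the natural log of the cell count;
#' the paper-style summary also reports the SNR ratio between the largest
#' and smallest cell counts (mean SNR per count).
#'
#' @param cell_counts,snr numeric vectors (>= 3 distinct cell counts).
#' @return object of class `snr_trend`: `slope`, `intercept`, `r_squared`,
#'   `ratio_max_min`, and the per-count `points` data.frame.
#' @export
snr_trend <- function(cell_counts, snr) {
  stopifnot(length(cell_counts) == length(snr))
  ok <- !is.na(snr)
  cell_counts <- cell_counts[ok]; snr <- snr[ok]
  if (length(unique(cell_counts)) < 3)
    abort("need at least 3 distinct cell counts for the SNR trend")
  fit <- stats::lm(snr ~ log(cell_counts))
  mean_by <- stats::aggregate(snr, by = list(cell_count = cell_counts), FUN = mean)
  names(mean_by)[2] <- "snr"
  lo <- mean_by$snr[which.min(mean_by$cell_count)]
  hi <- mean_by$snr[which.max(mean_by$cell_count)]
  tss <- sum((snr - mean(snr))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 ratio_max_min = hi / lo,
                 points = mean_by),
            class = "snr_trend")
}

#' @export
print.snr_trend <- function(x, ...) {
  cat(sprintf("<snr_trend> SNR = %.3f + %.3f*ln(cells) (R2=%.3f); SNR(max)/SNR(min)=%.2f\n",
              x$intercept, x$slope, x$r_squared, x$ratio_max_min))
  invisible(x)
}
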