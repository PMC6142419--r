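# Copy-number / LoH detection from allelic imbalance. The pipeline mirrors
# heterozygous allele frequencies below 0.5 to the equal distance above,
# median-filters them over a neighborhood of variants, and compares the
# smoothed level against the noise of user-designated copy-neutral
# chromosomes; losses and copy-neutral LoH are detected as depletion of
# mid-range allele frequencies. Gaussian kernel density estimation with the
# Silverman bandwidth provides the mode structure (bimodal for a disomy --
# het at 1/2 plus hom-alt at 1 -- trimodal for a trisomy: 1/3, 2/3, 1).

#' Per-chromosome VAF series
#'
#' Depth-filtered VAFs in positional order. With a second replicate, sites
#' called in both contribute the mean of the two VAFs (replicate-mean mode);
#' sites seen in only one replicate keep their single value.
#'
#' @param replicate an `assay_replicate`.
#' @param chromosome chromosome label.
#' @param replicate_b optional second replicate for replicate-mean VAFs.
#' @param min_depth inclusive DP threshold (default 30).
#' @return a `data.frame` with `pos`, `vaf`, `genotype`; zero rows when no
#'   call qualifies.
#' @export
chrom_vaf_series <- function(replicate, chromosome, replicate_b = NULL,
                             min_depth = 30) {
  stopifnot(inherits(replicate, "assay_replicate"))
  one <- function(r) {
    r <- filter_depth(r, min_depth)
    calls <- r$calls[r$calls$chrom == chromosome, , drop = FALSE]
    calls <- calls[order(calls$pos), , drop = FALSE]
    data.frame(pos = calls$pos,
               vaf = suppressWarnings(vaf(calls$ad_ref, calls$ad_alt)),
               genotype = calls$genotype, stringsAsFactors = FALSE)
  }
  a <- one(replicate)
  if (is.null(replicate_b)) {
    out <- a[!is.na(a$vaf), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  b <- one(replicate_b)
  m <- merge(a, b, by = "pos", all = TRUE, suffixes = c("_a", "_b"))
  v <- rowMeans(cbind(m$vaf_a, m$vaf_b), na.rm = TRUE)
  gt <- ifelse(!is.na(m$genotype_a), m$genotype_a, m$genotype_b)
  out <- data.frame(pos = m$pos, vaf = v, genotype = gt, stringsAsFactors = FALSE)
  out <- out[!is.na(out$vaf), , drop = FALSE]
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mirror allele frequencies about 0.5
#'
#' Values below 0.5 are reflected to the equal distance above (v -> 1 - v);
#' values at or above 0.5 are unchanged, so the output lies in [0.5, 1].
#' Pooling the symmetric imbalance signal this way improves its
#' signal-to-noise ratio.
#'
#' @param values numeric vector in [0, 1].
#' @return the mirrored values.
#' @export
mirror_af <- function(values) {
  if (any(values < 0 | values > 1, na.rm = TRUE))
    abort("allele frequencies must lie in [0, 1]")
  ifelse(values < 0.5, 1 - values, values)
}

#' Median filter over a variant neighborhood
#'
#' Each value is replaced by the median of the window of neighboring
#' variants centered on it (half-width `floor(window / 2)` on each side),
#' truncated at the series ends; the series length is preserved and
#' chromosome boundaries are never crossed (the filter operates on one
#' chromosome's series at a time).
#'
#' @param values numeric vector (one chromosome's VAF series).
#' @param window neighborhood range in variants (default 100).
#' @return the filtered vector, same length.
#' @export
median_filter <- function(values, window = 100) {
  if (!is_count(window) || window < 1) abort("window must be a positive integer")
  n <- length(values)
  if (n == 0) abort("cannot median-filter an empty series")
  h <- floor(window / 2)
  vapply(seq_len(n), function(i)
    stats::median(values[max(1L, i - h):min(n, i + h)]), numeric(1))
}

#' Silverman's rule-of-thumb bandwidth
#'
#' h = (4 * sigma^5 / (3 * n))^(1/5) with sigma the sample standard
#' deviation.
#'
#' @param values numeric vector, n >= 2 with positive dispersion.
#' @return the bandwidth.
#' @export
silverman_bandwidth <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) abort("need at least 2 values for a bandwidth")
  s <- stats::sd(values)
  if (s == 0) abort("zero dispersion: Silverman bandwidth undefined")
  (4 * s^5 / (3 * n))^(1 / 5)
}

#' Gaussian kernel density estimate
#'
#' Exact kernel sum (no binning): density(x) = (1 / (n h)) * sum phi((x - v_i) / h)
#' with phi the standard Gaussian. The profile also carries a peak-scaled
#' copy (density divided by its maximum, so the highest peak equals 1) for
#' relative comparison across samples.
#'
#' @param values numeric vector (allele frequencies).
#' @param h bandwidth; [silverman_bandwidth()] of the values when `NULL`.
#' @param grid evaluation grid; default 512 points on [-0.1, 1.1] so modes
#'   at the boundary of [0, 1] are resolved.
#' @return object of class `kde_profile`: `grid`, `density`,
#'   `density_scaled`, `h`, `n`.
#' @export
kde <- function(values, h = NULL, grid = seq(-0.1, 1.1, length.out = 512)) {
  values <- values[!is.na(values)]
  if (!length(values)) abort("cannot estimate a density from no values")
  if (is.null(h)) h <- silverman_bandwidth(values)
  if (h <= 0) abort("bandwidth must be positive")
  dens <- rowMeans(stats::dnorm(outer(grid, values, "-") / h)) / h
  structure(list(grid = grid, density = dens,
                 density_scaled = dens / max(dens), h = h, n = length(values)),
            class = "kde_profile")
}

#' Detect density modes by prominence
#'
#' Local maxima of the density whose topographic prominence (height above
#' the higher of the two flanking bases, where a base is the minimum between
#' the peak and the nearest higher point on that side) exceeds
#' `prominence_fraction` times the global maximum.
#'
#' @param profile a `kde_profile` on a grid of >= 64 points.
#' @param prominence_fraction minimum prominence as a fraction of the global
#'   maximum (default 0.1).
#' @return list with `locations` (grid positions of the modes) and `count`.
#' @export
detect_modes <- function(profile, prominence_fraction = 0.1) {
  stopifnot(inherits(profile, "kde_profile"))
  y <- profile$density
  if (length(y) < 64) abort("grid too coarse for mode detection (need >= 64 points)")
  n <- length(y)
  peaks <- which(diff(sign(diff(y))) < 0) + 1L
  if (!length(peaks)) return(list(locations = numeric(0), count = 0L))
  prom <- vapply(peaks, function(i) {
    left_hi <- which(y[seq_len(i - 1)] > y[i])
    lb <- if (length(left_hi)) max(left_hi) else 1L
    right_hi <- which(y[(i + 1):n] > y[i])
    rb <- if (length(right_hi)) i + min(right_hi) else n
    y[i] - max(min(y[lb:i]), min(y[i:rb]))
  }, numeric(1))
  keep <- prom > prominence_fraction * max(y)
  list(locations = profile$grid[peaks[keep]], count = sum(keep))
}

#' Default thresholds for the CNA caller
#'
#' @param window median-filter / segmentation window in variants.
#' @param gain_z multiples of the (scaled) neutral noise the smoothed
#'   mirrored-het level must exceed the neutral level by to call a gain.
#' @param loss_factor a chromosome or window is depleted when its fraction
#'   of VAFs in the mid-range [0.2, 0.8] falls below `loss_factor` times the
#'   neutral chromosomes' fraction.
#' @param min_het minimum het calls for a gain evaluation.
#' @param min_run_windows consecutive depleted/elevated windows (stride =
#'   window / 2) required for a sub-chromosomal segment call; the default of
#'   2 means events spanning fewer than ~`window` variants are not called --
#'   the sensitivity cost of filtering at this scale.
#' @param prominence_fraction passed to [detect_modes()].
#' @return a list of thresholds.
#' @export
cna_config <- function(window = 100, gain_z = 3, loss_factor = 1 / 3,
                       min_het = 30, min_run_windows = 2,
                       prominence_fraction = 0.1) {
  list(window = window, gain_z = gain_z, loss_factor = loss_factor,
       min_het = min_het, min_run_windows = min_run_windows,
       prominence_fraction = prominence_fraction)
}

# fraction of VAFs in the heterozygous mid-range
mid_fraction <- function(v) if (length(v)) mean(v >= 0.2 & v <= 0.8) else NA_real_

# segment runs of TRUE at least min_run long -> (start,end) window indices
runs_at_least <- function(flag, min_run) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  data.frame(start = starts[keep], end = ends[keep])
}

#' Call copy-number state from allelic imbalance
#'
#' Whole-chromosome calls plus sub-chromosomal segment calls over fixed-size
#' variant windows. Gains are detected as an elevated median-filtered
#' mirrored-het level relative to the designated neutral chromosomes' own
#' level and noise; losses and copy-neutral LoH (indistinguishable from
#' allele frequencies alone) as depletion of mid-range VAFs. KDE mode counts
#' are reported as corroborating evidence.
#'
#' @param replicate an `assay_replicate`.
#' @param neutral_chroms chromosomes assumed free of allelic imbalance, used
#'   as the noise reference (default `chr2`, `chr3`).
#' @param replicate_b optional second replicate; VAFs are then replicate
#'   means.
#' @param min_depth inclusive DP threshold (default 30).
#' @param config thresholds from [cna_config()].
#' @return a `data.frame` of calls: `chrom`, `segment` (`"whole"` or a
#'   `start-end` variant-index range), `call` (`neutral` / `gain` /
#'   `loss_or_cnloh`), `n_variants`, and evidence columns
#'   (`filtered_median`, `gain_threshold`, `mid_frac`, `neutral_mid_frac`,
#'   `n_modes`).
#' @export
call_cna <- function(replicate, neutral_chroms = c("chr2", "chr3"),
                     replicate_b = NULL, min_depth = 30,
                     config = cna_config()) {
  stopifnot(inherits(replicate, "assay_replicate"))
  chroms <- unique(replicate$calls$chrom)
  series <- lapply(chroms, function(ch)
    chrom_vaf_series(replicate, ch, replicate_b = replicate_b,
                     min_depth = min_depth))
  names(series) <- chroms

  # neutral reference: pooled mirrored het VAFs and pooled mid-range fraction
  neutral_present <- intersect(neutral_chroms, chroms)
  if (!length(neutral_present))
    abort("none of the neutral chromosomes (%s) has qualifying calls",
          paste(neutral_chroms, collapse = ", "))
  neutral_het <- unlist(lapply(series[neutral_present], function(s)
    s$vaf[s$genotype == "het"]))
  neutral_all <- unlist(lapply(series[neutral_present], function(s) s$vaf))
  if (length(neutral_het) < 2) abort("too few neutral het calls for a noise reference")
  nm <- mirror_af(neutral_het)
  m0 <- mean(nm)
  s0 <- stats::sd(nm)
  f0 <- mid_fraction(neutral_all)

  rows <- list()
  for (ch in chroms) {
    s <- series[[ch]]
    n_all <- nrow(s)
    if (n_all == 0) next
    het_idx <- which(s$genotype == "het")
    n_het <- length(het_idx)
    # gain evidence: median-filtered mirrored het level vs neutral level
    filt_med <- NA_real_
    gain_thr <- NA_real_
    gain_whole <- FALSE
    filt <- NULL
    if (n_het >= config$min_het) {
      mir <- mirror_af(s$vaf[het_idx])
      filt <- median_filter(mir, config$window)
      # the whole-chromosome statistic averages over n_het values, so its
      # standard error scales with sqrt(n_het), not the filter window
      gain_thr <- m0 + config$gain_z * s0 / sqrt(n_het)
      filt_med <- mean(filt)
      gain_whole <- filt_med > gain_thr
    }
    # loss evidence: depletion of mid-range VAFs
    mf <- mid_fraction(s$vaf)
    loss_whole <- is.finite(f0) && f0 > 0 && mf < config$loss_factor * f0
    # corroborating KDE modality over all VAFs of the chromosome
    n_modes <- NA_integer_
    if (n_all >= 8 && stats::sd(s$vaf) > 0) {
      prof <- kde(s$vaf)
      n_modes <- detect_modes(prof, config$prominence_fraction)$count
    }
    call <- if (gain_whole) "gain" else if (loss_whole) "loss_or_cnloh" else "neutral"
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ch, segment = "whole", call = call, n_variants = n_all,
      filtered_median = filt_med, gain_threshold = gain_thr,
      mid_frac = mf, neutral_mid_frac = f0, n_modes = n_modes,
      stringsAsFactors = FALSE)

    # windowed sub-chromosomal calls over all calls (stride = window / 2)
    w <- config$window
    stride <- max(1L, floor(w / 2))
    if (n_all >= 2 * w) {
      starts <- seq(1L, n_all - w + 1L, by = stride)
      win_mid <- vapply(starts, function(i) mid_fraction(s$vaf[i:(i + w - 1L)]),
                        numeric(1))
      low <- is.finite(win_mid) & f0 > 0 & win_mid < config$loss_factor * f0
      low_runs <- runs_at_least(low, config$min_run_windows)
      for (rr in seq_len(nrow(low_runs))) {
        run <- low_runs[rr, ]
        i1 <- starts[run$start]; i2 <- starts[run$end] + w - 1L
        # a whole-chromosome gain call does not veto loss segments: mixed
        # chromosomes (p-arm loss + q-arm gain) carry both signals
        if (!(loss_whole && i2 - i1 + 1L >= 0.9 * n_all))
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = ch, segment = sprintf("%d-%d", i1, i2),
            call = "loss_or_cnloh", n_variants = i2 - i1 + 1L,
            filtered_median = NA_real_, gain_threshold = NA_real_,
            mid_frac = mean(win_mid[run$start:run$end]),
            neutral_mid_frac = f0, n_modes = NA_integer_,
            stringsAsFactors = FALSE)
      }
      # windowed gain calls on the filtered mirrored het track
      if (!is.null(filt) && n_het >= 2 * w) {
        win_thr <- m0 + config$gain_z * s0 / sqrt(w)
        hstarts <- seq(1L, n_het - w + 1L, by = stride)
        win_gain <- vapply(hstarts, function(i)
          mean(filt[i:(i + w - 1L)]), numeric(1)) > win_thr
        gr <- runs_at_least(win_gain, config$min_run_windows)
        for (rr in seq_len(nrow(gr))) {
          i1 <- het_idx[hstarts[gr$start[rr]]]
          i2 <- het_idx[min(hstarts[gr$end[rr]] + w - 1L, n_het)]
          if (!gain_whole)
            rows[[length(rows) + 1L]] <- data.frame(
              chrom = ch, segment = sprintf("%d-%d", i1, i2), call = "gain",
              n_variants = i2 - i1 + 1L, filtered_median = NA_real_,
              gain_threshold = gain_thr, mid_frac = NA_real_,
              neutral_mid_frac = f0, n_modes = NA_integer_,
              stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
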