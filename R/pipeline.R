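# End-to-end orchestration: simulate (or ingest) a dilution series, apply
# the standard filters, and assemble the concordance / SNR / CNA QC report.

#' Pipeline configuration
#'
#' @param mode `"simulate"` (run the forward simulator) or `"analyze"`
#'   (ingest existing VCFs described by `samples`).
#' @param sim a [simulation_config()] (simulate mode).
#' @param samples data.frame with `path`, `cell_count`, `replicate`
#'   (analyze mode).
#' @param regions optional region data.frame (or BED path) restricting all
#'   analyses to target regions.
#' @param min_depth inclusive DP threshold for SNR and CNA analyses.
#' @param neutral_chroms CNA-free chromosomes used as the noise reference.
#' @param str_ratio_threshold STR peak-imbalance ratio.
#' @param cna cna thresholds from [cna_config()].
#' @param seed integer seed recorded in (and driving) every report.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "analyze"),
                            sim = NULL, samples = NULL, regions = NULL,
                            min_depth = 30,
                            neutral_chroms = c("chr2", "chr3"),
                            str_ratio_threshold = 3,
                            cna = cna_config(),
                            seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "simulate") {
    if (is.null(sim)) sim <- simulation_config(seed = seed)
  } else {
    if (is.null(samples) || !all(c("path", "cell_count", "replicate") %in% names(samples)))
      abort("analyze mode needs a samples table with path, cell_count, replicate")
    missing <- !file.exists(samples$path)
    if (any(missing))
      abort("missing input file(s): %s", paste(samples$path[missing], collapse = ", "))
  }
  if (is.character(regions)) regions <- read_bed(regions)
  structure(list(mode = mode, sim = sim, samples = samples, regions = regions,
                 min_depth = min_depth, neutral_chroms = neutral_chroms,
                 str_ratio_threshold = str_ratio_threshold, cna = cna,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the QC pipeline
#'
#' Stages: simulate/ingest, filter (PASS, optional regions), replicate
#' concordance with exponential fit and genotype-likelihood correlation
#' against the highest-input replicate, heterozygous-AF SNR with normality
#' and log-linear trend, STR dropout scoring (simulate mode), and CNA
#' calling. A failed stage is recorded under `errors` and the remaining
#' stages still run. Deterministic given the configuration seed.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `qc_report` (a nested list of tables; see
#'   [render_report()]).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  errors <- list()
  # stage wrapper: on error, record the message and keep going
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  if (config$mode == "simulate") {
    fx <- simulate_fixture_set(config$sim)
    reps <- fx$replicates
  } else {
    reps <- lapply(seq_len(nrow(config$samples)), function(i)
      read_vcf(config$samples$path[i],
               cell_count = config$samples$cell_count[i],
               replicate_index = config$samples$replicate[i]))
    names(reps) <- vapply(reps, function(r) r$sample_id, "")
    fx <- NULL
  }

  reps <- lapply(reps, filter_pass)
  if (!is.null(config$regions))
    reps <- lapply(reps, restrict_to_regions, regions = config$regions)

  cells <- vapply(reps, function(r) as.integer(r$cell_count), 1L)

  # --- concordance ---
  concordance <- run_stage("concordance", {
    summaries <- list()
    for (cc in sort(unique(cells))) {
      group <- reps[cells == cc]
      if (length(group) >= 2)
        for (i in seq_len(length(group) - 1))
          summaries[[length(summaries) + 1L]] <-
            mismatch_fraction(group[[i]], group[[i + 1]])
    }
    if (!length(summaries)) abort("no replicate pairs: concordance unavailable")
    curve <- mismatch_curve(summaries)
    fit <- if (nrow(curve) >= 3)
      fit_exponential(curve$cell_count, curve$mismatch) else NULL
    table <- do.call(rbind, lapply(summaries, function(s)
      data.frame(cell_count = s$cell_count, n_sites = s$n_sites,
                 concordant = s$counts$concordant, loh = s$counts$loh,
                 allele_change = s$counts$allele_change,
                 total_dropout = s$counts$total_dropout,
                 mismatch = s$mismatch_fraction)))
    # genotype-likelihood correlation of each assay vs the top-input replicate
    anchor <- reps[[which(cells == max(cells))[1]]]
    gl <- do.call(rbind, lapply(reps, function(r) {
      if (identical(r$sample_id, anchor$sample_id)) return(NULL)
      res <- tryCatch(genotype_likelihood_correlation(r, anchor),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(sample = r$sample_id, cell_count = r$cell_count,
                 rho = res$rho, n_shared = res$n_shared)
    }))
    list(summaries = table, curve = curve,
         fit = if (!is.null(fit)) list(a = fit$a, b = fit$b, c = fit$c,
                                       r_squared = fit$r_squared) else NULL,
         gl_correlation = gl)
  })

  # --- SNR ---
  af <- run_stage("af_statistics", {
    tab <- do.call(rbind, lapply(reps, function(r) {
      v <- het_af_values(r, config$neutral_chroms, config$min_depth)
      if (length(v) < 8) return(NULL)
      s <- compute_snr(v)
      nt <- test_normality(v)
      data.frame(sample = r$sample_id, cell_count = r$cell_count, n = s$n,
                 mu = s$mu, sigma = s$sigma, snr = s$snr, cv = s$cv,
                 ad_statistic = nt$statistic, normality_pass = nt$pass)
    }))
    if (is.null(tab)) abort("no replicate with enough het calls on neutral chromosomes")
    trend <- if (length(unique(tab$cell_count)) >= 3)
      snr_trend(tab$cell_count, tab$snr) else NULL
    list(table = tab,
         trend = if (!is.null(trend)) list(slope = trend$slope,
                                           intercept = trend$intercept,
                                           r_squared = trend$r_squared,
                                           ratio_max_min = trend$ratio_max_min)
                 else NULL)
  })

  # --- STR (simulate mode carries a panel) ---
  str_table <- NULL
  if (!is.null(fx)) {
    str_table <- run_stage("str", {
      do.call(rbind, lapply(split(fx$str, list(fx$str$cell_count, fx$str$replicate)),
                            function(obs) {
        if (!nrow(obs)) return(NULL)
        cmp <- compare_str(fx$str_reference, obs, config$str_ratio_threshold)
        data.frame(cell_count = obs$cell_count[1], replicate = obs$replicate[1],
                   n_affected = cmp$n_affected,
                   full_dropout = sum(cmp$comparisons$status == "full_dropout"),
                   complete_loh = sum(cmp$comparisons$status == "complete_loh"),
                   partial_dropout = sum(cmp$comparisons$status == "partial_dropout"))
      }))
    })
  }

  # --- CNA ---
  cna_table <- run_stage("cna", {
    out <- do.call(rbind, lapply(reps, function(r) {
      calls <- tryCatch(call_cna(r, neutral_chroms = config$neutral_chroms,
                                 min_depth = config$min_depth,
                                 config = config$cna),
                        error = function(e) NULL)
      if (is.null(calls)) return(NULL)
      cbind(data.frame(sample = r$sample_id, cell_count = r$cell_count), calls)
    }))
    if (is.null(out)) abort("CNA calling produced no output")
    out
  })

  provenance <- list(seed = config$seed, mode = config$mode,
                     min_depth = config$min_depth,
                     neutral_chroms = config$neutral_chroms,
                     package_version = as.character(utils::packageVersion("mdaqc")),
                     config_hash = config_hash(config))
  structure(list(concordance = concordance, af_statistics = af,
                 str = str_table, cna = cna_table,
                 errors = errors, provenance = provenance),
            class = "qc_report")
}

# md5 of the canonical JSON serialization of the config (function elements
# and genome/site tables reduced to their defining scalars)
config_hash <- function(config) {
  skel <- list(mode = config$mode, seed = config$seed,
               min_depth = config$min_depth,
               neutral_chroms = config$neutral_chroms,
               str_ratio_threshold = config$str_ratio_threshold,
               cna = config$cna,
               sim = if (!is.null(config$sim))
                 list(cell_counts = config$sim$cell_counts,
                      replicates = config$sim$replicates_per_count,
                      seed = config$sim$seed,
                      model = unclass(config$sim$model)) else NULL,
               samples = config$samples)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(skel, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Render a QC report
#'
#' @param report a `qc_report`.
#' @param format `"json"` (canonical, lossless), `"tsv"` (one file per
#'   table) or `"markdown"` (human-readable summary).
#' @param out_dir output directory (created if needed).
#' @return character vector of the files written.
#' @export
render_report <- function(report, format = c("json", "tsv", "markdown"),
                          out_dir = ".") {
  stopifnot(inherits(report, "qc_report"))
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "json") {
    path <- file.path(out_dir, "qc_report.json")
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    return(path)
  }
  if (format == "tsv") {
    files <- character(0)
    tabs <- list(mismatch = report$concordance$summaries,
                 mismatch_curve = report$concordance$curve,
                 gl_correlation = report$concordance$gl_correlation,
                 snr = report$af_statistics$table,
                 str = report$str, cna = report$cna)
    for (nm in names(tabs)) {
      if (is.null(tabs[[nm]])) next
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      utils::write.table(tabs[[nm]], f, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      files <- c(files, f)
    }
    return(files)
  }
  # markdown
  path <- file.path(out_dir, "qc_report.md")
  lines <- c("# Sparse-cell WGA QC report", "",
             sprintf("- seed: %d", report$provenance$seed),
             sprintf("- config hash: %s", report$provenance$config_hash), "")
  if (!is.null(report$concordance)) {
    lines <- c(lines, "## Replicate mismatch vs cell input", "",
               utils::capture.output(print(report$concordance$curve,
                                           row.names = FALSE)), "")
    if (!is.null(report$concordance$fit))
      lines <- c(lines, sprintf(
        "Exponential fit: %.3f * exp(-%.3f x) + %.3f (R^2 = %.3f)",
        report$concordance$fit$a, report$concordance$fit$b,
        report$concordance$fit$c, report$concordance$fit$r_squared), "")
  } else lines <- c(lines, "## Replicate mismatch: unavailable", "")
  if (!is.null(report$af_statistics)) {
    lines <- c(lines, "## Heterozygous-AF signal-to-noise", "",
               utils::capture.output(print(report$af_statistics$table,
                                           row.names = FALSE)), "")
  }
  if (!is.null(report$cna)) {
    called <- report$cna[report$cna$call != "neutral", , drop = FALSE]
    lines <- c(lines, "## CNA calls (non-neutral)", "",
               utils::capture.output(print(called, row.names = FALSE)), "")
  }
  if (length(report$errors))
    lines <- c(lines, "## Stage errors", "",
               sprintf("- %s: %s", names(report$errors),
                       unlist(report$errors)), "")
  writeLines(lines, path)
  path
}
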