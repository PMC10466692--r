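#' Pipeline run configuration
#'
#' Bundles the global constants of a screening run: genome scale and bin
#' size, equal-read window count, Z threshold, segmentation settings, the
#' fetal-fraction lower detection limit, the confidence-interval method and
#' the CNV overlap rule.
#'
#' @param genome_scale Linear genome scale factor.
#' @param bin_size Bin width in bp.
#' @param n_windows Equal-read window count for [make_windows()].
#' @param z_threshold Aneuploidy positivity threshold.
#' @param segmentation A [segmentation_config()].
#' @param ff_lod Fetal-fraction lower detection limit (default 0.035).
#' @param ci_method Confidence-interval method for [compute_metrics()].
#' @param overlap CNV reciprocal-overlap matching threshold.
#' @param depth Default simulated depth.
#' @param seed Default seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(genome_scale = 1 / 20, bin_size = 5e4,
                       n_windows = 3000L, z_threshold = 3,
                       segmentation = segmentation_config(),
                       ff_lod = 0.035, ci_method = "wilson_cc",
                       overlap = 0.25, depth = 8.5e6, seed = 1L) {
  if (z_threshold <= 0) stopf("`z_threshold` must be > 0")
  if (ff_lod <= 0 || ff_lod >= 1) stopf("`ff_lod` must be in (0, 1)")
  if (overlap <= 0 || overlap > 1) stopf("`overlap` must be in (0, 1]")
  structure(list(genome_scale = genome_scale, bin_size = bin_size,
                 n_windows = as.integer(n_windows), z_threshold = z_threshold,
                 segmentation = segmentation, ff_lod = ff_lod,
                 ci_method = ci_method, overlap = overlap, depth = depth,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML document
#'
#' Keys mirror the arguments of [run_config()]; `segmentation` may be a
#' nested mapping with [segmentation_config()] keys. Unknown keys are
#' rejected.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(doc), known)
  if (length(bad)) stopf("unknown config key: %s", bad[1])
  if (!is.null(doc$segmentation)) {
    doc$segmentation <- do.call(segmentation_config, doc$segmentation)
  }
  do.call(run_config, doc)
}

read_tsv_checked <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
    stopf("empty or schema-less file: %s", path)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0 && ncol(df) <= 1) stopf("empty or schema-less file: %s", path)
  miss <- setdiff(required, names(df))
  if (length(miss)) stopf("missing required column '%s' in %s", miss[1], path)
  for (cl in intersect(numeric_cols, names(df))) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & v != "NA")
      if (length(bad)) {
        stopf("malformed numeric value in column '%s', row %d of %s",
              cl, bad[1], path)
      }
      df[[cl]] <- conv
    }
  }
  df
}

#' Read / write a bin table as TSV
#'
#' Columns `chrom`, `start`, `end`, `gc`, `raw_count` (0-based half-open
#' intervals), plus `relative_reads` / `corrected_ratio` when present.
#' Round-trips losslessly to well below 1e-12 relative error; both LF and
#' CRLF files are accepted.
#'
#' @param path File path.
#' @return `read_bintable` returns the data frame; `write_bintable` returns
#'   `path` invisibly.
#' @export
read_bintable <- function(path) {
  read_tsv_checked(path, c("chrom", "start", "end", "gc", "raw_count"),
                   c("start", "end", "gc", "raw_count", "relative_reads",
                     "corrected_ratio"))
}

#' @rdname read_bintable
#' @param table A bin table data frame.
#' @export
write_bintable <- function(table, path) {
  df <- table
  for (cl in names(df)) {
    if (is.numeric(df[[cl]])) df[[cl]] <- format(df[[cl]], digits = 17, trim = TRUE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a fragment profile as TSV
#'
#' Columns `chrom`, `start`, `end`, `n_short_100_150`, `n_total` and
#' (optionally) `gc`.
#' @param path File path.
#' @export
read_fragment_profile <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "n_short_100_150",
                                 "n_total"),
                         c("start", "end", "n_short_100_150", "n_total", "gc"))
  if (any(df$n_short_100_150 > df$n_total)) {
    stopf("short-fragment count exceeds total in %s", path)
  }
  df
}

#' @rdname read_fragment_profile
#' @param profile A fragment profile data frame.
#' @export
write_fragment_profile <- function(profile, path) {
  write_bintable(profile, path)
}

#' Read a concordance count fixture
#'
#' Fixtures are TSV tables with a `label` column and any of the count
#' columns `n_screen_positive`, `n_confirmed`, `n_diagnostic_positive`,
#' `n_detected`, `n_maternal`, `n_larger`, `stratum`. Negative counts are
#' rejected; unexpected columns are kept with a warning.
#'
#' @param path Path to the fixture (see
#'   `system.file("extdata", package = "cfscreen")` for the packaged ones).
#' @return Data frame of validated counts.
#' @export
read_fixture <- function(path) {
  count_cols <- c("n_screen_positive", "n_confirmed", "n_diagnostic_positive",
                  "n_detected", "n_maternal", "n_larger")
  df <- read_tsv_checked(path, "label", count_cols)
  known <- c("label", "stratum", count_cols)
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    warnf("ignoring unexpected fixture column(s): %s",
          paste(extra, collapse = ", "))
  }
  for (cl in intersect(count_cols, names(df))) {
    v <- df[[cl]]
    if (any(v < 0, na.rm = TRUE)) stopf("negative count in column '%s'", cl)
  }
  df
}

#' Path of a packaged fixture
#'
#' @param name Fixture file name (e.g. `"aneuploidy_ppv_counts.tsv"`); with
#'   no argument, lists available fixtures.
#' @return Full path, or a character vector of names.
#' @export
cfscreen_fixture <- function(name = NULL) {
  dir <- system.file("extdata", package = "cfscreen")
  if (is.null(name)) return(list.files(dir))
  path <- file.path(dir, name)
  if (!file.exists(path)) stopf("no packaged fixture '%s'", name)
  path
}

#' Write CNV calls as a BED file
#'
#' 0-based half-open coordinates, sorted by chromosome and start; name is
#' the call state plus origin, score the segment Z (capped at 1000).
#'
#' @param calls A CNV call data frame (see [call_cnvs()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(calls, path) {
  if (!nrow(calls)) {
    file.create(path)
    return(invisible(path))
  }
  ord <- order(calls$chromosome, calls$start_bp)
  calls <- calls[ord, , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.", calls$chromosome,
                   as.integer(calls$start_bp), as.integer(calls$end_bp),
                   paste0(calls$state, "_", calls$origin),
                   pmin(1000L, as.integer(round(calls$segment_z * 10))))
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated truth record as JSON
#'
#' Events, compartments, fetal fraction, seed and the rendered diagnostic
#' strings of a `sim_truth`.
#'
#' @param truth A `sim_truth`.
#' @param genome The genome it was simulated on.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, genome, path) {
  ev_list <- function(evs, fracs) {
    lapply(seq_along(evs), function(i) {
      e <- evs[[i]]
      list(chromosome = e$chromosome, start = e$start, end = e$end,
           copy_number = e$copy_number, label = e$label,
           mosaic_fraction = if (length(fracs)) fracs[i] else 1)
    })
  }
  dx <- truth_to_diagnostic(truth, genome)
  obj <- list(sample_id = truth$sample_id,
              fetal_fraction = truth$fetal_fraction,
              fetal_sex = truth$fetal_sex,
              fetal_events = ev_list(truth$fetal_events, truth$fetal_mosaic_fraction),
              placental_events = ev_list(truth$placental_events,
                                         truth$placental_mosaic_fraction),
              maternal_events = ev_list(truth$maternal_events, NULL),
              seed = truth$seed,
              diagnostic_strings = as.character(dx$raw))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a concordance report to disk
#'
#' Emits `metrics.tsv`, `counts.tsv` and `report.json` under `dir`.
#'
#' @param report A [build_report()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "concordance_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$metrics, file.path(dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$counts)) {
    utils::write.table(report$counts, file.path(dir, "counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(metrics = report$metrics, counts = report$counts),
                       file.path(dir, "report.json"), digits = NA,
                       dataframe = "rows")
  invisible(dir)
}
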