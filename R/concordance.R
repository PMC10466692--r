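#' Construct a diagnostic finding
#'
#' One microarray-style finding: an interval copy-number state (possibly a
#' mosaic range) or a whole-karyotype call. Coordinates are stored 0-based
#' half-open; the printed (1-based inclusive) form is produced by
#' [format_iscn()].
#'
#' @param chrom Chromosome name.
#' @param start,end Interval, 0-based half-open.
#' @param cn_low,cn_high Copy-number bounds; equal unless mosaic.
#' @param mosaic Logical.
#' @param chrom_length Binned chromosome length used for the
#'   whole-chromosome test; defaults to the GRCh37 callable length.
#' @param karyotype Whole-karyotype token (`"45,X"` etc.) when known.
#' @param roh Logical: region of homozygosity (never screenable).
#' @param raw The source string, if parsed.
#' @return A one-row data frame with a `category` column.
#' @export
diagnostic_finding <- function(chrom, start, end, cn_low, cn_high = cn_low,
                               mosaic = cn_low != cn_high,
                               chrom_length = NULL, karyotype = NA_character_,
                               roh = FALSE, raw = NA_character_) {
  chrom <- norm_chrom(chrom)
  if (start >= end) stopf("finding start must be < end")
  if (is.null(chrom_length)) chrom_length <- grch37_callable_length(chrom)
  category <- classify_finding(chrom, start, end, cn_low, cn_high,
                               chrom_length, karyotype, roh)
  if (is.na(karyotype) && category == "SCA") {
    karyotype <- sca_karyotype_from_finding(chrom, cn_low, cn_high)
  }
  f <- data.frame(chrom = chrom, start = as.numeric(start),
                  end = as.numeric(end), cn_low = as.integer(cn_low),
                  cn_high = as.integer(cn_high), mosaic = mosaic,
                  category = category, karyotype = karyotype, roh = roh,
                  raw = raw, stringsAsFactors = FALSE)
  f$raw[is.na(f$raw)] <- format_iscn(f)
  f
}

# Category of a finding: aneuploidy when the interval covers >= 90% of the
# chromosome's binned length, else an interval CNV; ROH and karyotype tokens
# short-circuit.
classify_finding <- function(chrom, start, end, cn_low, cn_high,
                             chrom_length, karyotype, roh) {
  if (isTRUE(roh)) return("ROH")
  if (!is.na(karyotype)) return("SCA")
  whole <- (end - start) >= 0.9 * chrom_length
  cn_eff <- if (cn_high > 2) cn_high else cn_low  # direction of the change
  if (whole && chrom %in% c("chrX", "chrY")) {
    if (chrom == "chrX" && cn_eff %in% c(1L, 3L)) return("SCA")
    if (chrom == "chrY" && cn_eff == 2L) return("SCA")
    if (chrom == "chrX" && cn_low == 2L && cn_high == 2L) return("SCA")
    return(if (cn_eff > 2) "CNV_dup" else "CNV_del")
  }
  if (whole && cn_eff == 3L) {
    chr_num <- sub("chr", "", chrom)
    return(switch(chr_num, "21" = "T21", "18" = "T18", "13" = "T13",
                  paste0("RAT_", chrom)))
  }
  if (cn_eff > 2) "CNV_dup" else if (cn_eff < 2) "CNV_del" else "ROH"
}

sca_karyotype_from_finding <- function(chrom, cn_low, cn_high) {
  cn_eff <- if (cn_high > 2) cn_high else cn_low
  if (chrom == "chrX") {
    switch(as.character(cn_eff), "1" = "45,X", "3" = "47,XXX",
           "2" = NA_character_, NA_character_)
  } else if (chrom == "chrY" && cn_eff == 2L) {
    "47,XYY"
  } else {
    NA_character_
  }
}

#' Bundle findings into a set
#'
#' @param findings List of [diagnostic_finding()] rows (or a data frame).
#' @param sample_id Sample identifier.
#' @return A data frame of class `diagnostic_finding_set` (zero rows allowed).
#' @export
diagnostic_finding_set <- function(findings = list(), sample_id = NA_character_) {
  df <- if (is.data.frame(findings)) {
    findings
  } else if (length(findings)) {
    do.call(rbind, findings)
  } else {
    diagnostic_finding("chr1", 0, 1, 1)[0, ]
  }
  structure(df, sample_id = sample_id,
            class = c("diagnostic_finding_set", "data.frame"))
}

#' Parse an ISCN-style microarray result string
#'
#' Accepts the `arr[GRCh37] <bands>(<start>_<end>)x<cn>` dialect with
#' thousands separators, mosaic copy-number ranges (`x2-3`, en dash,
#' hyphen or underscore), an optional `hmz` homozygosity token, and
#' whole-karyotype tokens (`45,X`/`45,XO`, `47,XXY`, `47,XXX`, `47,XYY`) and
#' bare trisomy tokens (`T21`). Printed coordinates are 1-based inclusive
#' and converted to the internal 0-based half-open convention.
#'
#' @param raw The result string.
#' @return A [diagnostic_finding()] row.
#' @examples
#' parse_iscn("arr[GRCh37] 21q11.2q22.3(15,016,486_48,093,361)×3")$category
#' @export
parse_iscn <- function(raw) {
  s <- gsub("\\s+", "", raw)
  # whole-karyotype tokens
  if (grepl("^4[57],", s)) {
    kar <- switch(toupper(s), "45,X" = "45,X", "45,XO" = "45,X",
                  "47,XXY" = "47,XXY", "47,XXX" = "47,XXX",
                  "47,XYY" = "47,XYY", NULL)
    if (is.null(kar)) stopf("unrecognised karyotype token: %s", raw)
    chrom <- if (kar == "47,XYY") "chrY" else "chrX"
    cn <- switch(kar, "45,X" = 1L, "47,XXX" = 3L, "47,XXY" = 2L, "47,XYY" = 2L)
    return(diagnostic_finding(chrom, 0, grch37_lengths[[chrom]], cn,
                              karyotype = kar, raw = raw))
  }
  if (grepl("^T[0-9]{1,2}$", s)) {
    chrom <- norm_chrom(sub("^T", "", s))
    if (!chrom %in% names(grch37_lengths)) stopf("unknown chromosome in token: %s", raw)
    return(diagnostic_finding(chrom, grch37_callable_start[[chrom]],
                              grch37_lengths[[chrom]], 3L, raw = raw))
  }
  pat <- paste0("^arr\\[GRCh37\\]\\]?",                 # header (tolerate ']]' typo)
                "(chr)?([0-9]{1,2}|X|Y)",               # chromosome
                "((?:[pq][0-9.]+){0,2})",               # optional band token
                "\\(([0-9,]+)_([0-9,]+)\\)",            # printed coordinates
                "[×xX]([0-9]+)",                   # copy number
                "(?:[–—_-]([0-9]+))?",        # mosaic upper bound
                "(hmz)?$")
  m <- regmatches(s, regexec(pat, s))[[1]]
  if (!length(m)) {
    stopf("malformed ISCN string (offending token: '%s')",
          substr(s, 1, 40))
  }
  chrom <- norm_chrom(m[3])
  if (!chrom %in% names(grch37_lengths)) stopf("unknown chromosome: %s", m[3])
  start1 <- as.numeric(gsub(",", "", m[5]))
  end1 <- as.numeric(gsub(",", "", m[6]))
  if (start1 >= end1) stopf("finding start must be < end ('%s')", raw)
  cn1 <- as.integer(m[7])
  cn2 <- if (nzchar(m[8])) as.integer(m[8]) else cn1
  roh <- nzchar(m[9]) || (cn1 == 2L && cn2 == 2L)
  diagnostic_finding(chrom, start1 - 1, end1, min(cn1, cn2), max(cn1, cn2),
                     mosaic = cn1 != cn2, roh = roh, raw = raw)
}

#' Format a finding in the canonical ISCN-like dialect
#'
#' Karyotype-level findings print their token; interval findings print
#' `arr[GRCh37] <chrom>(<start>_<end>)x<cn>` (band-free) with 1-based
#' inclusive, comma-separated coordinates and an en-dashed mosaic range.
#' `format_iscn(parse_iscn(s))` is idempotent.
#'
#' @param f A [diagnostic_finding()] row.
#' @return Character string.
#' @export
format_iscn <- function(f) {
  if (!is.na(f$karyotype) && f$category == "SCA" && !f$mosaic &&
      f$end - f$start >= 0.9 * grch37_callable_length(f$chrom)[1] &&
      f$start == 0) {
    # prefer the interval rendering when coordinates are informative;
    # fall through for parsed karyotype tokens (full chromosome span)
    if (f$end == grch37_lengths[[f$chrom]]) return(f$karyotype)
  }
  num <- function(x) format(x, big.mark = ",", scientific = FALSE, trim = TRUE)
  cn <- if (f$cn_low == f$cn_high) {
    as.character(f$cn_low)
  } else {
    paste0(f$cn_low, "–", f$cn_high)
  }
  paste0("arr[GRCh37] ", sub("chr", "", f$chrom), "(", num(f$start + 1), "_",
         num(f$end), ")×", cn, if (isTRUE(f$roh)) " hmz" else "")
}

#' Size of an interval finding in megabases
#'
#' The span between the first and last covered base pair — the printed-
#' coordinate subtraction used when array findings are sized.
#'
#' @param f A [diagnostic_finding()] row (interval-scoped).
#' @return Size in Mb; `NA` for karyotype-level findings.
#' @export
finding_size_mb <- function(f) {
  if (!is.na(f$karyotype) && f$category == "SCA") return(NA_real_)
  (f$end - f$start - 1) / 1e6
}

# Concordance -----------------------------------------------------------------

#' Match screening calls against diagnostic findings
#'
#' Aneuploidies are matched by chromosome identity, sex-chromosome
#' karyotypes by token identity, CNVs by sign and reciprocal overlap.
#' Unmatched screening calls are false positives, unmatched diagnostic
#' findings false negatives; a category empty on both sides is a true
#' negative. Diagnostic deletions below 0.5 Mb and duplications below 1 Mb
#' fall under the microarray selection floor and are excluded; ROH findings
#' are never screenable and are classified `NS`.
#'
#' @param screening A [screen_sample()] result.
#' @param diagnostic A [diagnostic_finding_set()].
#' @param overlap Reciprocal-overlap threshold for CNV matching
#'   (default 0.25).
#' @return Data frame with columns `category`, `class`
#'   (`TP`/`FP`/`FN`/`TN`/`NS`) and `detail`.
#' @export
match_calls <- function(screening, diagnostic, overlap = 0.25) {
  rows <- list()
  add <- function(category, class, detail = "") {
    rows[[length(rows) + 1L]] <<- data.frame(category = category,
                                             class = class, detail = detail,
                                             stringsAsFactors = FALSE)
  }
  dx <- as.data.frame(diagnostic)

  # --- autosomal aneuploidy, matched by chromosome
  aneu_cat <- function(chrom, call) {
    if (call == "monosomy") return(paste0("RAT_", chrom))
    switch(sub("chr", "", chrom), "21" = "T21", "18" = "T18", "13" = "T13",
           paste0("RAT_", chrom))
  }
  sc <- screening$aneuploidy_calls
  s_aneu <- if (nrow(sc)) {
    vapply(seq_len(nrow(sc)), function(i) aneu_cat(sc$chromosome[i], sc$call[i]),
           character(1))
  } else {
    character(0)
  }
  d_aneu <- dx$category[grepl("^T[0-9]+$|^RAT_", dx$category)]
  for (cat in union(s_aneu, d_aneu)) {
    in_s <- cat %in% s_aneu
    in_d <- cat %in% d_aneu
    add(if (grepl("^RAT_", cat)) "RAT" else cat,
        if (in_s && in_d) "TP" else if (in_s) "FP" else "FN",
        cat)
  }
  if (!length(union(s_aneu, d_aneu))) add("aneuploidy", "TN")

  # --- sex-chromosome karyotype, matched by token identity
  s_kar <- screening$sca_karyotype
  d_kar <- dx$karyotype[dx$category == "SCA" & !is.na(dx$karyotype)]
  s_has <- !is.na(s_kar) && !(s_kar %in% c("none", "no_call"))
  if (s_has || length(d_kar)) {
    if (s_has && length(d_kar) && s_kar %in% d_kar) {
      add("SCA", "TP", s_kar)
    } else {
      if (s_has) add("SCA", "FP", s_kar)
      if (length(d_kar)) add("SCA", "FN", d_kar[1])
    }
  } else {
    add("SCA", "TN")
  }

  # --- CNVs, matched by sign and reciprocal overlap
  d_cnv <- dx[grepl("^CNV_", dx$category), , drop = FALSE]
  if (nrow(d_cnv)) {
    sizes <- vapply(seq_len(nrow(d_cnv)), function(i)
      finding_size_mb(d_cnv[i, , drop = FALSE]), numeric(1))
    floor_mb <- ifelse(d_cnv$category == "CNV_del", 0.5, 1.0)
    d_cnv <- d_cnv[!is.na(sizes) & sizes >= floor_mb, , drop = FALSE]
  }
  s_cnv <- screening$cnv_calls
  used_s <- rep(FALSE, nrow(s_cnv))
  if (nrow(d_cnv)) {
    for (i in seq_len(nrow(d_cnv))) {
      sign_d <- if (d_cnv$category[i] == "CNV_dup") "dup" else "del"
      hit <- 0L
      for (j in seq_len(nrow(s_cnv))) {
        if (used_s[j] || s_cnv$state[j] != sign_d) next
        if (s_cnv$chromosome[j] != d_cnv$chrom[i]) next
        ov <- min(s_cnv$end_bp[j], d_cnv$end[i]) -
          max(s_cnv$start_bp[j], d_cnv$start[i])
        if (ov <= 0) next
        rec <- min(ov / (s_cnv$end_bp[j] - s_cnv$start_bp[j]),
                   ov / (d_cnv$end[i] - d_cnv$start[i]))
        if (rec >= overlap) { hit <- j; break }
      }
      if (hit > 0L) {
        used_s[hit] <- TRUE
        add("CNV", "TP", sprintf("%s %.2fMb", d_cnv$chrom[i],
                                 finding_size_mb(d_cnv[i, , drop = FALSE])))
      } else {
        add("CNV", "FN", sprintf("%s %.2fMb", d_cnv$chrom[i],
                                 finding_size_mb(d_cnv[i, , drop = FALSE])))
      }
    }
  }
  if (nrow(s_cnv)) {
    for (j in which(!used_s)) {
      add("CNV", "FP", sprintf("%s %s %.2fMb", s_cnv$chromosome[j],
                               s_cnv$state[j], s_cnv$size_mb[j]))
    }
  }
  if (!nrow(d_cnv) && !nrow(s_cnv)) add("CNV", "TN")

  # --- ROH: reported, never screenable
  n_roh <- sum(dx$category == "ROH")
  if (n_roh) add("ROH", "NS", sprintf("%d ROH finding(s)", n_roh))

  out <- do.call(rbind, rows)
  out$sample_id <- screening$sample_id %||% NA_character_
  out[, c("sample_id", "category", "class", "detail")]
}

#' Wilson score confidence interval for a proportion
#'
#' @param x Successes.
#' @param n Trials.
#' @param conf Confidence level.
#' @param method `"wilson_cc"` (Wilson with continuity correction, default),
#'   `"wilson"` or `"wald"`.
#' @return `c(low, high)` on the proportion scale.
#' @export
wilson_ci <- function(x, n, conf = 0.95,
                      method = c("wilson_cc", "wilson", "wald")) {
  method <- match.arg(method)
  if (n <= 0) return(c(NA_real_, NA_real_))
  p <- x / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- switch(method,
    wald = p + c(-1, 1) * z * sqrt(p * (1 - p) / n),
    wilson = {
      den <- 1 + z^2 / n
      ctr <- (p + z^2 / (2 * n)) / den
      hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
      c(ctr - hw, ctr + hw)
    },
    wilson_cc = {
      lo <- if (x == 0) 0 else {
        (2 * n * p + z^2 - 1 -
           z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) /
          (2 * (n + z^2))
      }
      hi <- if (x == n) 1 else {
        (2 * n * p + z^2 + 1 +
           z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) /
          (2 * (n + z^2))
      }
      c(lo, hi)
    })
  pmin(1, pmax(0, ci))
}

#' Compute a concordance metric row
#'
#' Sensitivity (`100 * detected / diagnostic-positive`), positive predictive
#' value (`100 * confirmed / screen-positive`), miss rate
#' (`100 - sensitivity`) and 95% confidence intervals.
#'
#' @param label Row label.
#' @param n_screen_positive,n_confirmed PPV numerator/denominator counts
#'   (`NA` when not applicable).
#' @param n_diagnostic_positive,n_detected Sensitivity counts.
#' @param ci_method Passed to [wilson_ci()].
#' @param conf Confidence level.
#' @return One-row data frame (`metric_row`): counts, `sensitivity`, `ppv`,
#'   `miss_rate` (percent), `ci_low`/`ci_high` (the sensitivity CI when
#'   defined, else the PPV CI) and `undefined` flag for zero denominators.
#' @examples
#' compute_metrics("T21", 31, 28, 29, 28)$ppv   # 90.32...
#' @export
compute_metrics <- function(label, n_screen_positive = NA, n_confirmed = NA,
                            n_diagnostic_positive = NA, n_detected = NA,
                            ci_method = "wilson_cc", conf = 0.95) {
  sens <- if (!is.na(n_diagnostic_positive) && n_diagnostic_positive > 0) {
    100 * n_detected / n_diagnostic_positive
  } else {
    NA_real_
  }
  ppv <- if (!is.na(n_screen_positive) && n_screen_positive > 0) {
    100 * n_confirmed / n_screen_positive
  } else {
    NA_real_
  }
  ci <- if (!is.na(sens)) {
    100 * wilson_ci(n_detected, n_diagnostic_positive, conf, ci_method)
  } else if (!is.na(ppv)) {
    100 * wilson_ci(n_confirmed, n_screen_positive, conf, ci_method)
  } else {
    c(NA_real_, NA_real_)
  }
  undef <- (!is.na(n_diagnostic_positive) && n_diagnostic_positive == 0) ||
    (!is.na(n_screen_positive) && n_screen_positive == 0)
  out <- data.frame(label = label,
                    n_screen_positive = n_screen_positive,
                    n_confirmed = n_confirmed,
                    n_diagnostic_positive = n_diagnostic_positive,
                    n_detected = n_detected,
                    sensitivity = sens, ppv = ppv,
                    miss_rate = if (is.na(sens)) NA_real_ else 100 - sens,
                    ci_low = ci[1], ci_high = ci[2],
                    undefined = undef, stringsAsFactors = FALSE)
  class(out) <- c("metric_row", "data.frame")
  out
}

#' Assign a CNV size stratum
#'
#' The reporting strata of size-resolved CNV sensitivity:
#' `[0.5, 1]`, `(1, 2]`, `(2, 3]`, `(3, 5]`, `(5, 10)` and `[10, Inf)` Mb.
#' Sizes below 0.5 Mb fall under the microarray selection floor and return
#' `NA` (excluded).
#'
#' @param size_mb Numeric vector of sizes in Mb.
#' @return Character vector of stratum labels (`NA` = excluded).
#' @examples
#' stratify_cnv(c(1, 10, 0.4))
#' @export
stratify_cnv <- function(size_mb) {
  labs <- cnv_strata_labels()
  out <- rep(NA_character_, length(size_mb))
  out[size_mb >= 0.5 & size_mb <= 1] <- labs[1]
  out[size_mb > 1 & size_mb <= 2] <- labs[2]
  out[size_mb > 2 & size_mb <= 3] <- labs[3]
  out[size_mb > 3 & size_mb <= 5] <- labs[4]
  out[size_mb > 5 & size_mb < 10] <- labs[5]
  out[size_mb >= 10] <- labs[6]
  out
}

#' CNV size stratum labels
#' @return Character vector of the six stratum labels, smallest first.
#' @export
cnv_strata_labels <- function() {
  c("500 kb to <=1 Mb", "1 to <=2 Mb", "2 to <=3 Mb", "3 to <=5 Mb",
    "5 to <=10 Mb", ">=10 Mb")
}

#' Canonical regions of common microdeletion/microduplication syndromes
#'
#' GRCh37 coordinates (0-based half-open) of the recurrent regions used to
#' annotate findings: 1p36 microdeletion, cri-du-chat (5p15), Williams-Beuren
#' (7q11.23), 9p deletion/duplication, Angelman/Prader-Willi (15q11-q13),
#' renal cysts and diabetes (RCAD, 17q12) and DiGeorge (22q11.2).
#'
#' @return Data frame with columns `name`, `chrom`, `start`, `end`, `sign`
#'   (`"del"`, `"dup"` or `"any"`).
#' @export
syndrome_regions <- function() {
  data.frame(
    name = c("1p36 microdeletion", "cri-du-chat (5p15)",
             "Williams-Beuren (7q11.23)", "9p deletion/duplication",
             "Angelman/Prader-Willi (15q11-q13)", "RCAD (17q12)",
             "DiGeorge (22q11.2)"),
    chrom = c("chr1", "chr5", "chr7", "chr9", "chr15", "chr17", "chr22"),
    start = c(0, 0, 72744454, 0, 23600000, 34815000, 18900000),
    end = c(10000000, 28900000, 74142513, 25000000, 28400000, 36215000,
            21900000),
    sign = c("del", "del", "del", "any", "del", "del", "del"),
    stringsAsFactors = FALSE)
}

#' Annotate a finding with a syndrome name
#'
#' A CNV finding is assigned a syndrome when its sign matches the region's
#' and it covers at least half of the canonical region.
#'
#' @param f A [diagnostic_finding()] row (interval CNV).
#' @param table A [syndrome_regions()] table.
#' @return The syndrome name, or `NA`.
#' @export
annotate_syndrome <- function(f, table = syndrome_regions()) {
  if (!grepl("^CNV_", f$category)) return(NA_character_)
  sign_f <- if (f$category == "CNV_dup") "dup" else "del"
  for (i in seq_len(nrow(table))) {
    if (table$chrom[i] != f$chrom) next
    if (table$sign[i] != "any" && table$sign[i] != sign_f) next
    ov <- min(f$end, table$end[i]) - max(f$start, table$start[i])
    if (ov >= 0.5 * (table$end[i] - table$start[i])) return(table$name[i])
  }
  NA_character_
}

#' Aggregate per-sample classifications into category counts
#'
#' @param class_list List of [match_calls()] data frames.
#' @return Data frame with columns `category`, `tp`, `fp`, `fn`, `tn`.
#' @export
aggregate_classifications <- function(class_list) {
  all <- do.call(rbind, class_list)
  cats <- sort(unique(all$category))
  do.call(rbind, lapply(cats, function(cat) {
    sub <- all[all$category == cat, ]
    data.frame(category = cat,
               tp = sum(sub$class == "TP"), fp = sum(sub$class == "FP"),
               fn = sum(sub$class == "FN"), tn = sum(sub$class == "TN"),
               stringsAsFactors = FALSE)
  }))
}

#' Build a concordance report
#'
#' Either summarises classified screening/diagnostic pairs from a simulated
#' cohort, or reproduces a count fixture (one metric row per fixture row,
#' plus a `Total` row when the fixture spans CNV strata).
#'
#' @param pairs List of [match_calls()] data frames (cohort mode).
#' @param fixture A fixture data frame from [read_fixture()] (fixture mode).
#' @param ci_method Passed to [compute_metrics()].
#' @return A list of class `concordance_report` with element `metrics`
#'   (a data frame of metric rows) and, in cohort mode, `counts`.
#' @export
build_report <- function(pairs = NULL, fixture = NULL,
                         ci_method = "wilson_cc") {
  if (is.null(pairs) == is.null(fixture)) {
    stopf("give exactly one of `pairs` or `fixture`")
  }
  if (!is.null(fixture)) {
    rows <- lapply(seq_len(nrow(fixture)), function(i) {
      compute_metrics(fixture$label[i],
                      fixture$n_screen_positive[i] %||% NA,
                      fixture$n_confirmed[i] %||% NA,
                      fixture$n_diagnostic_positive[i] %||% NA,
                      fixture$n_detected[i] %||% NA,
                      ci_method = ci_method)
    })
    metrics <- do.call(rbind, rows)
    return(structure(list(metrics = metrics, counts = fixture),
                     class = "concordance_report"))
  }
  counts <- aggregate_classifications(pairs)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    with(counts[i, ], compute_metrics(category,
                                      n_screen_positive = tp + fp,
                                      n_confirmed = tp,
                                      n_diagnostic_positive = tp + fn,
                                      n_detected = tp,
                                      ci_method = ci_method))
  })
  structure(list(metrics = do.call(rbind, rows), counts = counts),
            class = "concordance_report")
}
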