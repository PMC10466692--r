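#' Per-chromosome corrected read fractions
#'
#' The quantity the Z statistic standardises: each chromosome's share of the
#' GC-corrected read mass. Fractions sum to 1.
#'
#' @param bins A normalised bin table (see [normalize_bintable()]).
#' @return Named numeric vector of fractions, one per chromosome present.
#' @export
chromosome_fractions <- function(bins) {
  if (!("corrected_ratio" %in% names(bins))) {
    stopf("bin table lacks corrected ratios; run normalize_bintable() first")
  }
  s <- tapply(bins$corrected_ratio, bins$chrom, sum)
  if (any(is.na(s)) || any(s <= 0)) stopf("empty or zero-mass chromosome in bin table")
  f <- s / sum(s)
  f[unique(as.character(bins$chrom))]
}

# Inflation applied to the panel SD so that the |Z| >= z_cal rule attains its
# nominal normal tail despite mu and sigma being estimated from a finite
# panel: (x - mu_hat)/sd_hat is sqrt(1 + 1/n) * t_{n-1}, so dividing instead
# by sd_hat * c with c = sqrt(1 + 1/n) * qt(pnorm(z_cal), n - 1) / z_cal puts
# the threshold exactly at the normal z_cal tail.
panel_sd_inflation <- function(n, z_cal = 3) {
  sqrt(1 + 1 / n) * stats::qt(stats::pnorm(z_cal), df = n - 1) / z_cal
}

#' Build a euploid reference panel
#'
#' Per-chromosome mean and SD of the GC-corrected chromosomal read fraction
#' across a euploid training cohort. The stored SD is the raw cohort SD
#' inflated by a finite-panel factor calibrated at the calling threshold, so
#' that `z = (x - mean)/sd` has the nominal normal false-positive rate at
#' `|z| >= z_cal` (see the methods vignette); the uninflated SD is kept in
#' `sd_raw`.
#'
#' @param euploid_samples List of at least 20 normalised bin tables.
#' @param seed Optional integer recorded as panel metadata.
#' @param z_cal Calling threshold the SD calibration targets (default 3).
#' @return A data frame of class `reference_panel` with columns `chrom`,
#'   `mean`, `sd`, `sd_raw`; attributes `n`, `z_cal`, `seed`.
#' @export
build_panel <- function(euploid_samples, seed = NULL, z_cal = 3) {
  if (length(euploid_samples) < 20) stopf("need at least 20 euploid samples")
  fr <- t(vapply(euploid_samples, chromosome_fractions,
                 chromosome_fractions(euploid_samples[[1]])))
  mu <- colMeans(fr)
  sd_raw <- apply(fr, 2, stats::sd)
  if (any(sd_raw <= 0)) {
    stopf("degenerate panel: zero SD on %s", names(mu)[sd_raw <= 0][1])
  }
  n <- nrow(fr)
  panel <- data.frame(chrom = names(mu), mean = unname(mu),
                      sd = unname(sd_raw * panel_sd_inflation(n, z_cal)),
                      sd_raw = unname(sd_raw), stringsAsFactors = FALSE)
  structure(panel, n = n, z_cal = z_cal, seed = seed,
            class = c("reference_panel", "data.frame"))
}

#' Per-chromosome Z scores against a reference panel
#'
#' `z_c = (x_c - mu_c) / sigma_c` with the panel's reference mean and SD.
#'
#' @param sample_fractions Named fractions from [chromosome_fractions()].
#' @param panel A [build_panel()] panel covering every chromosome present.
#' @return Named numeric vector of Z scores.
#' @export
z_score <- function(sample_fractions, panel) {
  stopifnot(inherits(panel, "reference_panel"))
  miss <- setdiff(names(sample_fractions), panel$chrom)
  if (length(miss)) stopf("panel does not cover %s", miss[1])
  idx <- match(names(sample_fractions), panel$chrom)
  z <- (sample_fractions - panel$mean[idx]) / panel$sd[idx]
  stats::setNames(z, names(sample_fractions))
}

#' Call autosomal aneuploidies from Z scores
#'
#' A chromosome with `z >= threshold` is called trisomic and one with
#' `z <= -threshold` monosomic. The same rule serves the common trisomies
#' (21, 18, 13) and the rare autosomal trisomies.
#'
#' @param z Named Z scores; only `chr1`..`chr22` entries are considered.
#' @param threshold Positivity threshold (default 3).
#' @return Data frame with columns `chromosome`, `z`, `call` for chromosomes
#'   called (zero rows when all `|z|` are below threshold).
#' @export
call_autosomes <- function(z, threshold = 3) {
  auto <- paste0("chr", 1:22)
  z <- z[names(z) %in% auto]
  hit <- abs(z) >= threshold
  data.frame(chromosome = names(z)[hit], z = unname(z[hit]),
             call = ifelse(z[hit] > 0, "trisomy", "monosomy"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call a sex-chromosome karyotype
#'
#' Decision table over the chrX Z score, the chrY read fraction and the
#' fetal fraction: with no chrY material, a strongly negative `zx` is 45,X
#' and a strongly positive one 47,XXX; with chrY material, a strongly
#' positive `zx` is 47,XXY and a chrY share at least 1.5 times the single-Y
#' expectation for the measured fetal fraction is 47,XYY. Below the fetal
#' fraction detection limit no call is made.
#'
#' @param zx chrX Z score (against a male-adjusted expectation when chrY
#'   material is present — see [screen_sample()]).
#' @param zy chrY Z score (recorded, not used by the decision table).
#' @param y_fraction Observed chrY read fraction.
#' @param ff Fetal fraction estimate.
#' @param y_cal A [calibrate_y_reference()] result.
#' @param threshold Z threshold (default 3).
#' @param lod Fetal-fraction lower detection limit.
#' @param xyy_factor Multiple of the single-Y expectation above which a
#'   double-Y is called (default 1.5).
#' @return One of `"45,X"`, `"47,XXX"`, `"47,XXY"`, `"47,XYY"`, `"none"`,
#'   `"no_call"`.
#' @export
call_sex_chromosomes <- function(zx, zy, y_fraction, ff, y_cal,
                                 threshold = 3, lod = 0.035,
                                 xyy_factor = 1.5) {
  if (is.na(ff) || ff < lod) return("no_call")
  y_present <- y_fraction > y_cal$background_y + y_cal$noise_margin
  if (!y_present) {
    if (zx <= -threshold) return("45,X")
    if (zx >= threshold) return("47,XXX")
    return("none")
  }
  if (zx >= threshold) return("47,XXY")
  if (y_fraction >= xyy_factor * expected_y_fraction(ff, y_cal)) return("47,XYY")
  "none"
}

#' Screen one plasma sample end to end
#'
#' Runs the whole calling stack on a simulated (or read-in) sample:
#' normalisation, fetal-fraction estimation by both routes, per-chromosome
#' Z scores, autosomal trisomy/monosomy calls, sex-chromosome karyotype and
#' segmentation-based CNV calls with origin attribution. When chrY material
#' is present the chrX Z score used for the sex-chromosome decision is taken
#' against the male-typical expectation `mu_X * (1 - ff/2)`.
#'
#' @param sample A `sim_sample` (or list with `bins` and `profile`).
#' @param panel A [build_panel()] reference panel (euploid female cohort).
#' @param seqff_model A [train_seqff()] model.
#' @param y_cal A [calibrate_y_reference()] result.
#' @param config A [run_config()].
#' @return A list of class `screening_calls`: `sample_id`, `ff`
#'   (fetal-fraction estimate), `z` (all chromosomes), `aneuploidy_calls`,
#'   `sca_karyotype`, `cnv_calls`, `no_call`.
#' @export
screen_sample <- function(sample, panel, seqff_model, y_cal,
                          config = run_config()) {
  bins <- normalize_bintable(sample$bins)

  y_frac <- {
    y <- sample$bins$chrom == "chrY"
    sum(sample$bins$raw_count[y]) / sum(sample$bins$raw_count)
  }
  male_evidence <- y_frac > y_cal$background_y + y_cal$noise_margin
  ff_y <- estimate_ff_y(sample$bins, y_cal$background_y,
                        y_cal$male_reference_y, y_cal$noise_margin)
  ff_seqff <- as.numeric(estimate_ff_seqff(seqff_model, sample$profile))
  ff <- combine_ff(ff_y, ff_seqff, male_evidence, lod = config$ff_lod)
  # sex-chromosome dosage logic uses the chrY-independent estimate: an
  # aberrant Y dose (e.g. XYY) inflates ff_y and would corrupt both the
  # male-typical X expectation and the single-Y yardstick
  ff_sex <- if (!is.na(ff_seqff)) ff_seqff else ff$ff_combined

  x_base <- if (male_evidence && !is.na(ff_sex)) 1 - ff_sex / 2 else 1
  cnv <- call_sample_cnvs(bins, ff$ff_combined, config, x_baseline = x_base)

  # two-pass dosage analysis: a large called CNV both inflates its own
  # chromosome's read fraction (mimicking a trisomy) and, through the
  # genome-wide renormalisation, deflates every other chromosome's. Mask
  # such segments back to the diploid level, renormalise, and score
  # aneuploidy on the masked table. Only clearly non-fetal dosage is masked
  # (|deviation| >= 0.25 over >= 10 bins — the maternal scale, far beyond
  # what either count noise or a fetal-fraction-sized event produces over
  # that length), so the masked table keeps the noise structure the panel
  # was built on. A segment set covering most of a chromosome is the
  # aneuploidy itself and is left unmasked.
  masked <- bins
  big <- cnv[abs(cnv$mean_deviation) >= 0.25 & cnv$end_bp - cnv$start_bp >=
               10 * stats::median(bins$end - bins$start), , drop = FALSE]
  if (nrow(big)) {
    for (chr in setdiff(unique(big$chromosome), c("chrX", "chrY"))) {
      seg <- big[big$chromosome == chr, , drop = FALSE]
      on_chr <- masked$chrom == chr
      inside <- rep(FALSE, sum(on_chr))
      pos <- masked$start[on_chr]
      for (k in seq_len(nrow(seg))) {
        inside <- inside | (pos >= seg$start_bp[k] & pos < seg$end_bp[k])
      }
      if (mean(inside) < 0.8) {
        masked$corrected_ratio[on_chr][inside] <- 1
      }
    }
    masked$corrected_ratio <- masked$corrected_ratio /
      mean(masked$corrected_ratio)
  }
  fracs <- chromosome_fractions(masked)
  z <- z_score(fracs, panel)
  calls <- call_autosomes(z, threshold = config$z_threshold)
  # an unmasked (fetal-scale) CNV can still inflate its own chromosome's
  # fraction past the Z threshold. The CNV hypothesis asserts the rest of
  # the chromosome is diploid: keep the aneuploidy call only when the
  # uncalled remainder deviates too (or when called segments cover most of
  # the chromosome — a fractured whole-chromosome shift).
  if (nrow(calls) && nrow(cnv)) {
    keep <- vapply(seq_len(nrow(calls)), function(i) {
      chr <- calls$chromosome[i]
      seg <- cnv[cnv$chromosome == chr, , drop = FALSE]
      if (!nrow(seg)) return(TRUE)
      x <- bins$corrected_ratio[bins$chrom == chr]
      pos <- bins$start[bins$chrom == chr]
      inside <- rep(FALSE, length(x))
      for (k in seq_len(nrow(seg))) {
        inside <- inside | (pos >= seg$start_bp[k] & pos < seg$end_bp[k])
      }
      if (mean(inside) >= 0.8) return(TRUE)
      rem <- x[!inside]
      sigma <- stats::mad(diff(x)) / sqrt(2)
      if (!is.finite(sigma) || sigma <= 0) sigma <- stats::sd(x)
      abs(mean(rem) - 1) * sqrt(length(rem)) / sigma >= config$z_threshold
    }, logical(1))
    calls <- calls[keep, , drop = FALSE]
  }

  zx <- z[["chrX"]]
  if (male_evidence && !is.na(ff_sex)) {
    # male-typical X expectation at this fetal fraction
    i <- match("chrX", panel$chrom)
    zx <- (fracs[["chrX"]] - panel$mean[i] * (1 - ff_sex / 2)) / panel$sd[i]
  }
  sca <- call_sex_chromosomes(zx, z[["chrY"]], y_frac, ff_sex, y_cal,
                              threshold = config$z_threshold,
                              lod = config$ff_lod)

  # chromosomes already called aneuploid (or carrying the SCA) are not
  # re-reported as CNVs
  drop_chr <- calls$chromosome
  if (!sca %in% c("none", "no_call")) drop_chr <- c(drop_chr, "chrX", "chrY")
  if (nrow(cnv) && length(drop_chr)) {
    cnv <- cnv[!(cnv$chromosome %in% drop_chr), , drop = FALSE]
  }
  structure(list(sample_id = sample$sample_id %||% "sample",
                 ff = ff, z = z,
                 aneuploidy_calls = calls,
                 sca_karyotype = sca,
                 cnv_calls = cnv,
                 no_call = isTRUE(ff$below_lod) || isTRUE(ff$qc_fail)),
            class = "screening_calls")
}
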