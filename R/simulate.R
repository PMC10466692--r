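#' Define a genomic event (copy-number change)
#'
#' An event is a whole-chromosome or interval copy-number state applied to
#' one genomic compartment (maternal, placental or fetal) of a simulated
#' pregnancy.
#'
#' @param chromosome Chromosome name (`"chr21"` or `"21"`).
#' @param start,end Interval in bp, 0-based half-open; leave `NA` for a
#'   whole-chromosome event.
#' @param copy_number Integer copy number (2 is normal for autosomes, so
#'   events must have `copy_number != 2`).
#' @param label Optional label; guessed from scope and copy number when
#'   omitted (`"trisomy"`, `"monosomy"`, `"dup"`, `"del"`).
#' @return A list of class `genomic_event`.
#' @examples
#' genomic_event("chr21", copy_number = 3)                     # trisomy 21
#' genomic_event("chr7", 1e6, 2.5e6, copy_number = 1)          # 1.5 Mb del
#' @export
genomic_event <- function(chromosome, start = NA, end = NA, copy_number,
                          label = NULL) {
  chromosome <- norm_chrom(chromosome)
  if (!is_scalar_number(copy_number) || copy_number < 0 ||
      copy_number != round(copy_number)) {
    stopf("`copy_number` must be a non-negative integer")
  }
  whole <- is.na(start) && is.na(end)
  if (!whole) {
    if (is.na(start) || is.na(end)) stopf("give both `start` and `end`, or neither")
    if (start >= end) stopf("event start must be < end")
    if (start < 0) stopf("event start must be >= 0")
  }
  # 2 is the normal autosomal state; on X/Y the sex-typical base can be 0 or
  # 1, so copy number 2 is a legitimate event there (e.g. XXY: X = 2 in a male)
  if (copy_number == 2 && !(chromosome %in% c("chrX", "chrY"))) {
    stopf("an autosomal event must change copy number (copy_number != 2)")
  }
  if (is.null(label)) {
    label <- if (whole) {
      if (copy_number > 2) "trisomy" else "monosomy"
    } else {
      if (copy_number > 2) "dup" else "del"
    }
  }
  structure(list(chromosome = chromosome,
                 start = if (whole) NA_real_ else as.numeric(start),
                 end = if (whole) NA_real_ else as.numeric(end),
                 copy_number = as.integer(copy_number),
                 whole_chromosome = whole,
                 label = label),
            class = "genomic_event")
}

#' Specify a simulated maternal-plasma sample
#'
#' Bundles everything needed to synthesise one pregnancy: fetal fraction,
#' fetal sex, the copy-number events of the three compartments (maternal
#' genome, placental trophoblast, fetus), per-event mosaic fractions,
#' sequencing depth, GC bias and the count noise model. The plasma signal is
#' generated from the *placental* compartment mixed with the maternal
#' background; the diagnostic ground truth is the *fetal* compartment — the
#' separation that produces confined-placental-mosaicism discordance.
#'
#' @param sample_id Sample identifier.
#' @param fetal_fraction Proportion of plasma cfDNA of placental origin,
#'   in `[0, 1]`.
#' @param fetal_sex `"female"` or `"male"`.
#' @param fetal_events,placental_events,maternal_events Lists of
#'   [genomic_event()]s per compartment.
#' @param placental_mosaic_fraction,fetal_mosaic_fraction Mosaic fraction(s)
#'   in `[0, 1]`, recycled across the corresponding event list. A placental
#'   mosaic fraction pi blends the event into the trophoblast copy state as
#'   `(1 - pi) * base + pi * event`.
#' @param depth Expected total read count (default 8.5e6, the production
#'   assay's average effective volume of uniquely mapped reads).
#' @param gc_bias_coefficients `(intercept, slope)` of the simulated linear
#'   GC effect on expected bin intensity.
#' @param noise_model `"negative_binomial"` (default) or `"poisson"`.
#' @param dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); ignored for Poisson noise.
#' @param y_background Fraction of total reads misassigned to chrY bins
#'   irrespective of genotype (mapping noise floor that makes a female
#'   plasma sample carry a small chrY signal).
#' @param seed Integer seed; identical spec + seed gives bit-identical output.
#' @return A list of class `sim_sample_spec`.
#' @export
sim_sample_spec <- function(sample_id = "S1",
                            fetal_fraction = 0.2,
                            fetal_sex = c("female", "male"),
                            fetal_events = list(),
                            placental_events = list(),
                            maternal_events = list(),
                            placental_mosaic_fraction = 1,
                            fetal_mosaic_fraction = 1,
                            depth = 8.5e6,
                            gc_bias_coefficients = c(0.6, 1.0),
                            noise_model = c("negative_binomial", "poisson"),
                            dispersion = 0.01,
                            y_background = 5e-4,
                            seed = 1L) {
  fetal_sex <- match.arg(fetal_sex)
  noise_model <- match.arg(noise_model)
  check_proportion(fetal_fraction, "fetal_fraction")
  for (p in placental_mosaic_fraction) check_proportion(p, "placental_mosaic_fraction")
  for (p in fetal_mosaic_fraction) check_proportion(p, "fetal_mosaic_fraction")
  if (!is_scalar_number(depth) || depth <= 0) stopf("`depth` must be > 0")
  if (length(gc_bias_coefficients) != 2) stopf("`gc_bias_coefficients` must be (intercept, slope)")
  as_events <- function(ev) {
    if (inherits(ev, "genomic_event")) ev <- list(ev)
    if (!all(vapply(ev, inherits, logical(1), "genomic_event"))) {
      stopf("events must be genomic_event objects")
    }
    ev
  }
  fetal_events <- as_events(fetal_events)
  placental_events <- as_events(placental_events)
  maternal_events <- as_events(maternal_events)
  rec <- function(frac, ev) if (length(ev)) rep_len(frac, length(ev)) else numeric(0)
  structure(list(sample_id = as.character(sample_id),
                 fetal_fraction = fetal_fraction,
                 fetal_sex = fetal_sex,
                 fetal_events = fetal_events,
                 placental_events = placental_events,
                 maternal_events = maternal_events,
                 placental_mosaic_fraction = rec(placental_mosaic_fraction, placental_events),
                 fetal_mosaic_fraction = rec(fetal_mosaic_fraction, fetal_events),
                 depth = depth,
                 gc_bias_coefficients = as.numeric(gc_bias_coefficients),
                 noise_model = noise_model,
                 dispersion = dispersion,
                 y_background = y_background,
                 seed = as.integer(seed)),
            class = "sim_sample_spec")
}

# Per-bin copy-number vector for one compartment: sex-typical base blended
# with the compartment's events at their mosaic fractions.
copy_profile <- function(genome, base, events, mosaic) {
  cn <- base
  lens <- genome_chrom_lengths(genome)
  for (j in seq_along(events)) {
    ev <- events[[j]]
    if (!(ev$chromosome %in% names(lens))) {
      stopf("event chromosome %s not in genome", ev$chromosome)
    }
    on_chr <- genome$chrom == ev$chromosome
    idx <- if (ev$whole_chromosome) {
      on_chr
    } else {
      if (ev$end > lens[[ev$chromosome]]) {
        stopf("event %s:%d-%d extends beyond chromosome end (%d)",
              ev$chromosome, ev$start, ev$end, lens[[ev$chromosome]])
      }
      on_chr & genome$start < ev$end & genome$end > ev$start
    }
    pi <- if (length(mosaic)) mosaic[j] else 1
    cn[idx] <- (1 - pi) * cn[idx] + pi * ev$copy_number
  }
  cn
}

sex_base <- function(genome, sex) {
  base <- rep(2, nrow(genome))
  base[genome$chrom == "chrX"] <- if (sex == "male") 1 else 2
  base[genome$chrom == "chrY"] <- if (sex == "male") 1 else 0
  base
}

maternal_base <- function(genome) {
  base <- rep(2, nrow(genome))
  base[genome$chrom == "chrY"] <- 0
  base
}

#' Expected bin intensities for a sample specification
#'
#' Noise-free expectations of the simulator: the plasma copy ratio per bin,
#' the GC-weighted expected read count (summing exactly to `depth`), and the
#' locally fetal-derived share used for the fragment-length mixture.
#' The plasma copy ratio is
#' `(1 - ff) * m/2 + ff * ((1 - pi) * base + pi * k)/2`
#' with `m` the maternal copy number, `k` the placental event copy number and
#' `pi` the placental mosaic fraction.
#'
#' @param spec A [sim_sample_spec()].
#' @param genome A [synthetic_genome()].
#' @return A list with `plasma_ratio`, `mu` (expected counts), `fetal_share`
#'   and `p_short` (expected short-fragment proportion per bin).
#' @export
expected_bin_means <- function(spec, genome) {
  ff <- spec$fetal_fraction
  m <- copy_profile(genome, maternal_base(genome), spec$maternal_events,
                    rep(1, length(spec$maternal_events)))
  k <- copy_profile(genome, sex_base(genome, spec$fetal_sex),
                    spec$placental_events, spec$placental_mosaic_fraction)
  plasma <- (1 - ff) * m / 2 + ff * k / 2
  gc_eff <- pmax(0.05, spec$gc_bias_coefficients[1] +
                   spec$gc_bias_coefficients[2] * genome$gc)
  w <- gc_eff * plasma
  y_bins <- genome$chrom == "chrY"
  if (any(y_bins) && spec$y_background > 0) {
    w[y_bins] <- w[y_bins] + spec$y_background * sum(w) / sum(y_bins)
  }
  mu <- spec$depth * w / sum(w)
  fetal_share <- ifelse(plasma > 0, ff * k / 2 / plasma, 0)
  p <- frag_short_probs()
  p_short <- (1 - fetal_share) * p$maternal + fetal_share * p$fetal
  list(plasma_ratio = plasma, mu = mu, fetal_share = fetal_share,
       p_short = p_short)
}

# P(100 <= length <= 150) under the maternal and fetal truncated-normal
# fragment-length models: maternal N(166, 18), fetal N(143, 18) on [50, 250].
frag_short_probs <- function(maternal_mean = 166, fetal_mean = 143, sd = 18,
                             lower = 50, upper = 250, window = c(100, 150)) {
  trunc_prob <- function(mean) {
    denom <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
    (stats::pnorm(window[2], mean, sd) - stats::pnorm(window[1], mean, sd)) / denom
  }
  list(maternal = trunc_prob(maternal_mean), fetal = trunc_prob(fetal_mean))
}

#' Simulate one maternal-plasma sample
#'
#' Draws per-bin read counts from the specified noise model around the expected
#' intensities of [expected_bin_means()], a per-bin short-fragment count from
#' the fragment-length mixture, and records the fetal compartment as the
#' diagnostic ground truth.
#'
#' @param spec A [sim_sample_spec()].
#' @param genome A [synthetic_genome()].
#' @return A list of class `sim_sample` with elements `bins` (data.frame:
#'   `chrom`, `start`, `end`, `gc`, `raw_count`), `profile` (data.frame:
#'   `chrom`, `start`, `end`, `n_short_100_150`, `n_total`, `gc`) and
#'   `truth` (class `sim_truth`).
#' @examples
#' g <- synthetic_genome()
#' s <- simulate_sample(sim_sample_spec(seed = 7), g)
#' sum(s$bins$raw_count)
#' @export
simulate_sample <- function(spec, genome) {
  stopifnot(inherits(spec, "sim_sample_spec"), inherits(genome, "synthetic_genome"))
  if (spec$fetal_fraction == 0 && length(spec$fetal_events) > 0) {
    warnf("fetal_fraction is 0 with fetal events: undetectable by construction")
  }
  exp_means <- expected_bin_means(spec, genome)
  n <- nrow(genome)
  counts <- with_seed(spec$seed, {
    raw <- if (spec$noise_model == "poisson") {
      stats::rpois(n, exp_means$mu)
    } else {
      stats::rnbinom(n, size = 1 / spec$dispersion, mu = exp_means$mu)
    }
    short <- stats::rbinom(n, raw, exp_means$p_short)
    list(raw = raw, short = short)
  })
  bins <- data.frame(chrom = genome$chrom, start = genome$start,
                     end = genome$end, gc = genome$gc,
                     raw_count = counts$raw, stringsAsFactors = FALSE)
  profile <- data.frame(chrom = genome$chrom, start = genome$start,
                        end = genome$end,
                        n_short_100_150 = counts$short,
                        n_total = counts$raw, gc = genome$gc,
                        stringsAsFactors = FALSE)
  truth <- structure(list(sample_id = spec$sample_id,
                          fetal_fraction = spec$fetal_fraction,
                          fetal_sex = spec$fetal_sex,
                          fetal_events = spec$fetal_events,
                          fetal_mosaic_fraction = spec$fetal_mosaic_fraction,
                          placental_events = spec$placental_events,
                          placental_mosaic_fraction = spec$placental_mosaic_fraction,
                          maternal_events = spec$maternal_events,
                          seed = spec$seed),
                     class = "sim_truth")
  structure(list(bins = bins, profile = profile, truth = truth,
                 sample_id = spec$sample_id),
            class = "sim_sample")
}

# Scenario catalogue ---------------------------------------------------------

#' Build the sample spec for a named cohort scenario
#'
#' Scenarios encode the abnormality classes of a screening-vs-diagnosis
#' cohort: common trisomies, rare autosomal trisomies, sex-chromosome
#' aneuploidies, fetal and maternal sub-chromosomal CNVs, mosaic trisomy and
#' confined placental mosaicism (placental event, normal fetus).
#'
#' @param scenario One of `"euploid"`, `"t21"`, `"t18"`, `"t13"`, `"rat"`,
#'   `"45x"`, `"47xxx"`, `"47xxy"`, `"47xyy"`, `"mosaic_t21"`, `"cpm_t21"`,
#'   `"cpm_rat"`, `"fetal_cnv"`, `"maternal_cnv"`,
#'   `"maternal_cnv_uninherited"`.
#' @param sample_id Sample identifier.
#' @param genome A [synthetic_genome()].
#' @param ff Fetal fraction; drawn from the cohort distribution when `NULL`.
#' @param fetal_sex Fetal sex; scenario-appropriate default when `NULL`.
#' @param cnv_size_mb CNV size in Mb (CNV scenarios; default drawn
#'   uniformly from 0.5–10 Mb).
#' @param cnv_state `"del"` or `"dup"` (CNV scenarios).
#' @param chromosome Event chromosome (RAT/CNV scenarios; random default).
#' @param mosaic_fraction Mosaic fraction for `"mosaic_t21"` (default drawn
#'   uniformly from 0.1–0.4).
#' @param depth,seed,... Passed to [sim_sample_spec()].
#' @return A `sim_sample_spec`.
#' @export
scenario_sample_spec <- function(scenario, sample_id, genome,
                                 ff = NULL, fetal_sex = NULL,
                                 cnv_size_mb = NULL, cnv_state = NULL,
                                 chromosome = NULL, mosaic_fraction = NULL,
                                 depth = 8.5e6, seed = 1L, ...) {
  scenario <- match.arg(scenario, c("euploid", "t21", "t18", "t13", "rat",
                                    "45x", "47xxx", "47xxy", "47xyy",
                                    "mosaic_t21", "cpm_t21", "cpm_rat",
                                    "fetal_cnv", "maternal_cnv",
                                    "maternal_cnv_uninherited"))
  with_seed(child_seed(seed, 999L), {
    if (is.null(ff)) ff <- draw_fetal_fraction(1)
    if (is.null(fetal_sex)) {
      fetal_sex <- switch(scenario,
        "45x" = , "47xxx" = "female",
        "47xxy" = , "47xyy" = "male",
        sample(c("female", "male"), 1))
    }
    if (is.null(cnv_state)) cnv_state <- sample(c("del", "dup"), 1)
    if (is.null(mosaic_fraction)) mosaic_fraction <- stats::runif(1, 0.1, 0.4)
    rat_pool <- paste0("chr", setdiff(1:22, c(13, 18, 21)))
    if (is.null(chromosome)) {
      chromosome <- if (grepl("cnv", scenario)) {
        paste0("chr", sample(1:12, 1))
      } else {
        sample(rat_pool, 1)
      }
    }
    if (is.null(cnv_size_mb)) cnv_size_mb <- stats::runif(1, 0.5, 10)
    lens <- genome_chrom_lengths(genome)
    cnv_event <- function(cn) {
      size <- cnv_size_mb * 1e6
      len <- lens[[norm_chrom(chromosome)]]
      if (size >= len) stopf("CNV of %.1f Mb does not fit on %s", cnv_size_mb, chromosome)
      start <- floor(stats::runif(1, 0, len - size))
      genomic_event(chromosome, start, start + size, copy_number = cn)
    }
    tri <- function(chr) genomic_event(chr, copy_number = 3)
    args <- switch(scenario,
      euploid = list(),
      t21 = list(fetal_events = list(tri("chr21")),
                 placental_events = list(tri("chr21"))),
      t18 = list(fetal_events = list(tri("chr18")),
                 placental_events = list(tri("chr18"))),
      t13 = list(fetal_events = list(tri("chr13")),
                 placental_events = list(tri("chr13"))),
      rat = list(fetal_events = list(tri(chromosome)),
                 placental_events = list(tri(chromosome))),
      "45x" = list(fetal_events = list(genomic_event("chrX", copy_number = 1)),
                   placental_events = list(genomic_event("chrX", copy_number = 1))),
      "47xxx" = list(fetal_events = list(genomic_event("chrX", copy_number = 3)),
                     placental_events = list(genomic_event("chrX", copy_number = 3))),
      "47xxy" = list(fetal_events = list(genomic_event("chrX", copy_number = 2)),
                     placental_events = list(genomic_event("chrX", copy_number = 2))),
      "47xyy" = list(fetal_events = list(genomic_event("chrY", copy_number = 2)),
                     placental_events = list(genomic_event("chrY", copy_number = 2))),
      mosaic_t21 = list(fetal_events = list(tri("chr21")),
                        placental_events = list(tri("chr21")),
                        fetal_mosaic_fraction = mosaic_fraction,
                        placental_mosaic_fraction = mosaic_fraction),
      cpm_t21 = list(placental_events = list(tri("chr21"))),
      cpm_rat = list(placental_events = list(tri(chromosome))),
      fetal_cnv = {
        ev <- cnv_event(if (cnv_state == "del") 1L else 3L)
        list(fetal_events = list(ev), placental_events = list(ev))
      },
      maternal_cnv = {
        ev <- cnv_event(if (cnv_state == "del") 1L else 3L)
        list(fetal_events = list(ev), placental_events = list(ev),
             maternal_events = list(ev))
      },
      maternal_cnv_uninherited = {
        ev <- cnv_event(if (cnv_state == "del") 1L else 3L)
        list(maternal_events = list(ev))
      })
    do.call(sim_sample_spec,
            c(list(sample_id = sample_id, fetal_fraction = ff,
                   fetal_sex = fetal_sex, depth = depth, seed = seed),
              args, list(...)))
  })
}

#' Draw fetal fractions from the cohort distribution
#'
#' Beta(3, 10) truncated to `[0.042, 0.883]` — mean ~23% with the observed
#' clinical range of roughly 4–88%.
#'
#' @param n Number of draws.
#' @return Numeric vector of proportions.
#' @export
draw_fetal_fraction <- function(n) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rbeta(n, 3, 10)
    out <- c(out, x[x >= 0.042 & x <= 0.883])
  }
  out[seq_len(n)]
}

#' Simulate a cohort of maternal-plasma samples
#'
#' Assigns each of `n` samples a scenario drawn from `scenario_mix`
#' (prevalences; any remainder is euploid), draws per-sample fetal fractions
#' and sexes, and simulates each sample with a deterministic per-sample seed.
#'
#' @param n Number of samples (> 0).
#' @param scenario_mix Named numeric vector of scenario prevalences
#'   (see [scenario_sample_spec()] for names); must be non-negative and sum
#'   to at most 1.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param genome A [synthetic_genome()].
#' @param depth Expected reads per sample.
#' @param ... Extra arguments passed to [scenario_sample_spec()] (e.g.
#'   `cnv_size_mb`, `ff`).
#' @return A list of `sim_sample` objects; each carries its scenario name in
#'   the `scenario` element.
#' @export
simulate_cohort <- function(n, scenario_mix = c(euploid = 1), seed = 1L,
                            genome = synthetic_genome(), depth = 8.5e6, ...) {
  if (!is_scalar_number(n) || n <= 0 || n != round(n)) stopf("`n` must be a positive integer")
  if (any(scenario_mix < 0)) stopf("scenario prevalences must be >= 0")
  if (sum(scenario_mix) > 1 + 1e-12) stopf("scenario prevalences must sum to <= 1")
  mix <- c(scenario_mix)
  rest <- 1 - sum(mix)
  if (rest > 1e-12) {
    mix["euploid"] <- (mix["euploid"] %||% 0) + rest
    if (is.na(mix["euploid"])) mix["euploid"] <- rest
  }
  mix <- mix[mix > 0]
  scen <- with_seed(seed, sample(names(mix), n, replace = TRUE, prob = mix))
  lapply(seq_len(n), function(i) {
    sp <- scenario_sample_spec(scen[i], sample_id = sprintf("S%04d", i),
                               genome = genome, depth = depth,
                               seed = child_seed(seed, i), ...)
    out <- simulate_sample(sp, genome)
    out$scenario <- scen[i]
    out
  })
}

#' Render the fetal genotype of a simulated sample as diagnostic findings
#'
#' Applies microarray-style reporting to the fetal compartment of a
#' `sim_truth`: events at mosaic fraction below 0.1 are rounded to the
#' majority (normal) genotype and dropped, fractions in `[0.1, 0.9]` are
#' reported as a mosaic copy-number range (the "x2-3" style), higher
#' fractions as full events; interval findings below the reporting threshold
#' are suppressed. Sex-chromosome counts are folded into a karyotype call
#' (45,X; 47,XXX; 47,XXY; 47,XYY).
#'
#' @param truth A `sim_truth` (from [simulate_sample()]).
#' @param genome The [synthetic_genome()] the sample was simulated on.
#' @param min_size_bp Reporting threshold for interval findings (default
#'   100 kb, the microarray interpretation floor).
#' @return A [diagnostic_finding_set()] (possibly with zero rows).
#' @export
truth_to_diagnostic <- function(truth, genome, min_size_bp = 1e5) {
  stopifnot(inherits(truth, "sim_truth"))
  lens <- genome_chrom_lengths(genome)
  rows <- list()
  nX <- if (truth$fetal_sex == "male") 1L else 2L
  nY <- if (truth$fetal_sex == "male") 1L else 0L
  sex_mosaic <- NA_real_
  for (j in seq_along(truth$fetal_events)) {
    ev <- truth$fetal_events[[j]]
    f <- if (length(truth$fetal_mosaic_fraction)) truth$fetal_mosaic_fraction[j] else 1
    if (f < 0.1) next
    mosaic <- f <= 0.9
    if (ev$whole_chromosome && ev$chromosome %in% c("chrX", "chrY")) {
      if (ev$chromosome == "chrX") nX <- ev$copy_number else nY <- ev$copy_number
      sex_mosaic <- if (mosaic) f else NA_real_
      next
    }
    start <- if (ev$whole_chromosome) 0 else ev$start
    end <- if (ev$whole_chromosome) lens[[ev$chromosome]] else ev$end
    if (!ev$whole_chromosome && (end - start) < min_size_bp) next
    cn_low <- if (mosaic) min(2L, ev$copy_number) else ev$copy_number
    cn_high <- if (mosaic) max(2L, ev$copy_number) else ev$copy_number
    rows[[length(rows) + 1L]] <- diagnostic_finding(
      chrom = ev$chromosome, start = start, end = end,
      cn_low = cn_low, cn_high = cn_high, mosaic = mosaic,
      chrom_length = lens[[ev$chromosome]])
  }
  kar <- sex_karyotype(nX, nY)
  if (!is.na(kar)) {
    chrom <- if (kar %in% c("45,X", "47,XXX", "47,XXY")) "chrX" else "chrY"
    cn <- switch(kar, "45,X" = 1L, "47,XXX" = 3L, "47,XXY" = 2L, "47,XYY" = 2L)
    mosaic <- !is.na(sex_mosaic)
    rows[[length(rows) + 1L]] <- diagnostic_finding(
      chrom = chrom, start = 0, end = lens[[chrom]],
      cn_low = if (mosaic) min(2L, cn) else cn,
      cn_high = if (mosaic) max(2L, cn) else cn,
      mosaic = mosaic, chrom_length = lens[[chrom]], karyotype = kar)
  }
  diagnostic_finding_set(rows, sample_id = truth$sample_id)
}

# Karyotype implied by whole-genome X/Y copy counts; NA when sex-typical.
sex_karyotype <- function(nX, nY) {
  if (nX == 1 && nY == 0) return("45,X")
  if (nX == 3 && nY == 0) return("47,XXX")
  if (nX == 2 && nY == 1) return("47,XXY")
  if (nX == 1 && nY == 2) return("47,XYY")
  NA_character_
}
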