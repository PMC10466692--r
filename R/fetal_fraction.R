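#' Estimate fetal fraction from the chrY read share
#'
#' In a 46,XX mother every chrY read beyond the mapping-noise background must
#' be placental. The estimate rescales the observed chrY read fraction
#' between the female background and the pure-male reference:
#' `ff_y = (observed - background) / (male_reference - background)`,
#' clamped to `[0, 1]`. When the observed fraction is within the noise
#' margin of the background (a female fetus), the estimate is undefined.
#'
#' @param bins A bin table containing chrY bins (raw counts are used, so the
#'   estimate is invariant to uniform depth rescaling).
#' @param background_y Expected chrY read fraction of a female-fetus sample.
#' @param male_reference_y Expected chrY read fraction at fetal fraction 1.
#' @param noise_margin Margin above background below which the chrY signal
#'   is treated as absent (default: 4 background SDs, see
#'   [calibrate_y_reference()]).
#' @return Fetal fraction in `[0, 1]`, or `NA` (female fetus / no chrY bins).
#' @export
estimate_ff_y <- function(bins, background_y, male_reference_y,
                          noise_margin = 0) {
  if (background_y >= male_reference_y) {
    stopf("`background_y` must be below `male_reference_y`")
  }
  y <- bins$chrom == "chrY"
  if (!any(y)) {
    warnf("no chrY bins in table; chrY fetal fraction undefined")
    return(NA_real_)
  }
  obs <- sum(bins$raw_count[y]) / sum(bins$raw_count)
  if (obs <= background_y + noise_margin) return(NA_real_)
  min(1, max(0, (obs - background_y) / (male_reference_y - background_y)))
}

#' Self-calibrate the chrY reference fractions
#'
#' Measures `background_y` (pure-female syntheses) and `male_reference_y`
#' (fetal fraction 1, male) from the simulator itself, so the chrY estimator
#' needs no external reference panel.
#'
#' @param genome A [synthetic_genome()].
#' @param n Samples per calibration arm.
#' @param depth Reads per sample.
#' @param seed Integer seed.
#' @param ... Passed to [sim_sample_spec()] (e.g. `y_background`).
#' @return List with `background_y`, `background_sd`, `male_reference_y`,
#'   `noise_margin` (4 background SDs).
#' @export
calibrate_y_reference <- function(genome, n = 30L, depth = 8.5e6, seed = 1L,
                                  ...) {
  frac_y <- function(sex, ff, i) {
    s <- simulate_sample(sim_sample_spec(sample_id = sprintf("cal%d", i),
                                         fetal_fraction = ff, fetal_sex = sex,
                                         depth = depth,
                                         seed = child_seed(seed, i), ...),
                         genome)
    y <- s$bins$chrom == "chrY"
    sum(s$bins$raw_count[y]) / sum(s$bins$raw_count)
  }
  fem <- vapply(seq_len(n), function(i) frac_y("female", 0, i), numeric(1))
  mal <- vapply(seq_len(n), function(i) frac_y("male", 1, 1000L + i), numeric(1))
  list(background_y = mean(fem), background_sd = stats::sd(fem),
       male_reference_y = mean(mal),
       noise_margin = 4 * stats::sd(fem))
}

#' Expected chrY read fraction for a single-Y fetus
#'
#' Linear interpolation between the female background and the pure-male
#' reference at the measured fetal fraction — the yardstick against which a
#' double-Y (47,XYY) signal is judged.
#'
#' @param ff Fetal fraction.
#' @param y_cal A [calibrate_y_reference()] result.
#' @return Expected chrY read fraction.
#' @export
expected_y_fraction <- function(ff, y_cal) {
  y_cal$background_y + ff * (y_cal$male_reference_y - y_cal$background_y)
}

# Feature vector of the seqFF-style regression: genome-wide short-fragment
# proportion, mean GC, log total fragment count.
seqff_features <- function(profile) {
  req <- c("n_short_100_150", "n_total")
  if (!all(req %in% names(profile))) {
    stopf("fragment profile needs columns %s", paste(req, collapse = ", "))
  }
  tot <- sum(profile$n_total)
  if (tot <= 0) stopf("fragment profile has no fragments")
  gc <- if ("gc" %in% names(profile)) {
    sum(profile$gc * profile$n_total) / tot
  } else {
    NA_real_
  }
  c(short_prop = sum(profile$n_short_100_150) / tot,
    mean_gc = gc,
    log_reads = log(tot))
}

#' Train the seqFF-style fetal-fraction regression
#'
#' Ridge-regularised least squares of the known fetal fraction on three
#' sample-level features: the genome-wide proportion of short (100–150 bp)
#' fragments, the count-weighted mean GC and the log total fragment count.
#' Features are standardised before fitting; the ridge penalty (default
#' 1e-3) only stabilises near-collinear calibrations. If the feature matrix
#' is rank-deficient the fit falls back to a univariate regression on the
#' short-fragment proportion alone and is flagged.
#'
#' @param calibration List of `list(profile = <fragment profile>, ff = <true
#'   fetal fraction>)` pairs; at least 20.
#' @param lambda Ridge penalty on the standardised scale.
#' @return A list of class `seqff_model`: coefficients, feature
#'   standardisation constants, training ranges, `fallback` flag and
#'   training metadata.
#' @export
train_seqff <- function(calibration, lambda = 1e-3) {
  if (length(calibration) < 20) stopf("need at least 20 calibration samples")
  feats <- t(vapply(calibration, function(s) seqff_features(s$profile), numeric(3)))
  ff <- vapply(calibration, function(s) check_proportion(s$ff, "ff"), numeric(1))
  keep <- colSums(is.na(feats)) == 0
  feats <- feats[, keep, drop = FALSE]
  ctr <- colMeans(feats)
  scl <- apply(feats, 2, stats::sd)
  usable <- scl > 1e-12
  if (sum(usable) == 0) stopf("all features are constant; cannot train")
  # degenerate calibrations (only the short-fragment feature varies) take
  # the univariate fallback path and are flagged
  fallback <- sum(usable) == 1 && names(scl)[usable] == "short_prop" &&
    ncol(feats) > 1
  X <- scale(feats[, usable, drop = FALSE], center = ctr[usable], scale = scl[usable])
  XtX <- crossprod(X)
  # rank check on the standardised design
  ev <- eigen(XtX, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) / max(ev) < 1e-10 && "short_prop" %in% colnames(X)) {
    fallback <- TRUE
    X <- X[, "short_prop", drop = FALSE]
    XtX <- crossprod(X)
    usable <- colnames(feats) == "short_prop" & usable
  }
  beta <- solve(XtX + diag(lambda, ncol(X)), crossprod(X, ff - mean(ff)))
  structure(list(coefficients = drop(beta),
                 features = colnames(X),
                 center = ctr[colnames(X)],
                 scale = scl[colnames(X)],
                 intercept = mean(ff),
                 train_range = apply(feats, 2, range),
                 fallback = fallback,
                 n = length(calibration),
                 lambda = lambda),
            class = "seqff_model")
}

#' Estimate fetal fraction with a trained seqFF-style model
#'
#' @param model A [train_seqff()] model.
#' @param profile A fragment profile (per-bin short and total counts, plus
#'   `gc` when the model uses the GC feature).
#' @return Predicted fetal fraction clamped to `[0, 1]`; attribute
#'   `extrapolated` is `TRUE` when any feature lies outside the training
#'   range.
#' @export
estimate_ff_seqff <- function(model, profile) {
  stopifnot(inherits(model, "seqff_model"))
  f <- seqff_features(profile)[model$features]
  if (any(is.na(f))) stopf("profile lacks a feature required by the model (gc?)")
  z <- (f - model$center) / model$scale
  pred <- model$intercept + sum(z * model$coefficients)
  rng <- model$train_range[, model$features, drop = FALSE]
  extrap <- any(f < rng[1, ] | f > rng[2, ])
  structure(min(1, max(0, pred)), extrapolated = extrap)
}

#' Combine the chrY and seqFF fetal-fraction estimates
#'
#' With male-fetus evidence the two routes are averaged; otherwise the
#' seqFF estimate stands alone. The combined value is checked against the
#' lower detection limit (default 3.5%), below which the sample is a
#' screening no-call.
#'
#' @param ff_y chrY estimate (`NA` for a female fetus).
#' @param ff_seqff seqFF estimate (`NA` if unavailable).
#' @param male_evidence Logical: chrY material detected.
#' @param lod Lower detection limit for the fetal fraction.
#' @return A list of class `fetal_fraction_estimate`: `ff_y`, `ff_seqff`,
#'   `ff_combined`, `below_lod`, `lod`, `qc_fail`.
#' @examples
#' combine_ff(0.10, 0.12, male_evidence = TRUE)$ff_combined  # 0.11
#' @export
combine_ff <- function(ff_y, ff_seqff, male_evidence, lod = 0.035) {
  if (is.na(ff_y) && is.na(ff_seqff)) {
    return(structure(list(ff_y = NA_real_, ff_seqff = NA_real_,
                          ff_combined = NA_real_, below_lod = NA,
                          lod = lod, qc_fail = TRUE),
                     class = "fetal_fraction_estimate"))
  }
  combined <- if (isTRUE(male_evidence) && !is.na(ff_y) && !is.na(ff_seqff)) {
    mean(c(ff_y, ff_seqff))
  } else if (!is.na(ff_seqff)) {
    ff_seqff
  } else {
    ff_y
  }
  structure(list(ff_y = ff_y, ff_seqff = ff_seqff, ff_combined = combined,
                 below_lod = combined < lod, lod = lod, qc_fail = FALSE),
            class = "fetal_fraction_estimate")
}

#' Simulate a seqFF calibration set
#'
#' Convenience wrapper producing `(profile, ff)` pairs from the simulator
#' for [train_seqff()].
#'
#' @param n Number of calibration samples.
#' @param genome A [synthetic_genome()].
#' @param ff_range Range the true fetal fractions are drawn from (uniform).
#' @param depth Reads per sample.
#' @param seed Integer seed.
#' @return List of `list(profile, ff)` pairs.
#' @export
simulate_seqff_calibration <- function(n = 100L, genome = synthetic_genome(),
                                       ff_range = c(0.04, 0.30),
                                       depth = 8.5e6, seed = 1L) {
  ffs <- with_seed(seed, stats::runif(n, ff_range[1], ff_range[2]))
  sexes <- with_seed(child_seed(seed, 1L),
                     sample(c("female", "male"), n, replace = TRUE))
  lapply(seq_len(n), function(i) {
    s <- simulate_sample(sim_sample_spec(sample_id = sprintf("cal%03d", i),
                                         fetal_fraction = ffs[i],
                                         fetal_sex = sexes[i], depth = depth,
                                         seed = child_seed(seed, 10L + i)),
                         genome)
    list(profile = s$profile, ff = ffs[i])
  })
}
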