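#' Segmentation configuration
#'
#' Parameters of the least-squares changepoint segmentation and the dynamic
#' threshold that retains splits.
#'
#' @param z_t Dynamic-threshold multiplier: a split is kept only when a
#'   resulting segment's mean deviates from the diploid baseline by more
#'   than `z_t * sigma_hat / sqrt(L)` (default 3, matching the aneuploidy
#'   threshold).
#' @param min_bins Minimum bins per segment and per reported call.
#' @param max_depth Recursion cap of the binary splitting.
#' @param dev_floor Minimum |mean corrected ratio - 1| for a segment to be
#'   reported as a CNV call.
#' @param noise_estimator Robust per-bin noise estimator; `"mad_diff"`
#'   (scaled median absolute deviation of first differences) or `"sd"`.
#' @param multiplicity_adjust `FALSE` (default) applies `z_t` to each
#'   retained segment as is — the dynamic-threshold rule proper. `TRUE`
#'   instead controls the per-chromosome family-wise rate of spurious calls
#'   at the nominal level of `z_t` by Bonferroni-dividing it over the
#'   candidate segments a chromosome offers; this buys production-like
#'   specificity at the cost of sensitivity to small fetal events (see the
#'   methods vignette).
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(z_t = 3, min_bins = 3L, max_depth = 12L,
                                dev_floor = 0.015,
                                noise_estimator = c("mad_diff", "sd"),
                                multiplicity_adjust = FALSE) {
  noise_estimator <- match.arg(noise_estimator)
  if (z_t <= 0) stopf("`z_t` must be > 0")
  if (min_bins < 1) stopf("`min_bins` must be >= 1")
  structure(list(z_t = z_t, min_bins = as.integer(min_bins),
                 max_depth = as.integer(max_depth), dev_floor = dev_floor,
                 noise_estimator = noise_estimator,
                 multiplicity_adjust = multiplicity_adjust),
            class = "segmentation_config")
}

#' Robust per-bin noise estimate
#' @keywords internal
estimate_bin_noise <- function(x, estimator = "mad_diff") {
  s <- if (estimator == "mad_diff" && length(x) >= 3) {
    stats::mad(diff(x)) / sqrt(2)
  } else {
    stats::sd(x)
  }
  if (!is.finite(s) || s <= 0) s <- max(stats::sd(x), .Machine$double.eps)
  s
}

#' Segment one chromosome's corrected ratios
#'
#' Recursive binary splitting under a least-squares (sum-of-squared-error)
#' cost, grown to the minimum segment size and then pruned: candidate
#' boundaries are the SSE-minimising splits of the full recursion, and
#' adjacent segments are re-merged (weakest contrast first) until every
#' remaining boundary separates means that differ by more than `z_t`
#' standard errors of their difference, with `sigma_hat` the robust per-bin
#' noise. Growing before testing keeps an interior event from being diluted
#' in its parent's mean; pruning collapses uniform shifts (whole-chromosome
#' aneuploidy) to a single segment and stops pure noise from being peeled
#' into spikes. The dynamic threshold proper — a segment deviating from the
#' diploid baseline (corrected ratio 1) by more than
#' `z_t * sigma_hat / sqrt(L)` — is reported as `segment_z` and applied when
#' segments become calls. The output partitions the chromosome.
#'
#' @param ratios Numeric vector of corrected bin ratios for one chromosome.
#' @param cfg A [segmentation_config()].
#' @return Data frame with columns `start_bin`, `end_bin` (1-based
#'   inclusive bin indices), `n_bins`, `mean`, `mean_deviation`
#'   (`mean - 1`) and `segment_z` (`|mean - 1| * sqrt(n) / sigma_hat`);
#'   attribute `sigma` carries the noise estimate.
#' @export
segment_ratios <- function(ratios, cfg = segmentation_config()) {
  stopifnot(inherits(cfg, "segmentation_config"))
  n <- length(ratios)
  if (n < 1) stopf("no bins to segment")
  sigma <- estimate_bin_noise(ratios, cfg$noise_estimator)
  bounds <- integer(0)
  if (n >= 2 * cfg$min_bins) {
    cs <- c(0, cumsum(ratios))
    cs2 <- c(0, cumsum(ratios^2))
    seg_mean <- function(lo, hi) (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    grow <- function(lo, hi, depth) {
      len <- hi - lo + 1L
      if (len < 2L * cfg$min_bins || depth >= cfg$max_depth) return(NULL)
      splits <- (lo + cfg$min_bins - 1L):(hi - cfg$min_bins)
      nl <- splits - lo + 1L
      sl <- cs[splits + 1L] - cs[lo]
      ql <- cs2[splits + 1L] - cs2[lo]
      sser <- (cs2[hi + 1L] - cs2[splits + 1L]) -
        (cs[hi + 1L] - cs[splits + 1L])^2 / (hi - splits)
      ssel <- ql - sl^2 / nl
      s <- splits[which.min(ssel + sser)]
      list(s = s, lo = lo, hi = hi,
           left = grow(lo, s, depth + 1L),
           right = grow(s + 1L, hi, depth + 1L))
    }
    contrast_z <- function(lo, s, hi) {
      nl <- s - lo + 1L
      nr <- hi - s
      abs(seg_mean(lo, s) - seg_mean(s + 1L, hi)) /
        (sigma * sqrt(1 / nl + 1 / nr))
    }
    # prune the split tree bottom-up: a split survives when its full-span
    # left/right contrast is significant, or when surviving structure below
    # depends on it (removing it would fuse distinct segments)
    prune <- function(node) {
      if (is.null(node)) return(integer(0))
      below <- c(prune(node$left), prune(node$right))
      if (length(below) || contrast_z(node$lo, node$s, node$hi) >= cfg$z_t) {
        c(node$s, below)
      } else {
        integer(0)
      }
    }
    bounds <- sort(unique(prune(grow(1L, n, 0L))))
    # final pass on the consolidated segments: drop boundaries whose
    # adjacent means no longer differ significantly (weakest first)
    while (length(bounds)) {
      starts <- c(1L, bounds + 1L)
      ends <- c(bounds, n)
      m <- seg_mean(starts, ends)
      len <- ends - starts + 1L
      k <- length(bounds)
      zc <- abs(m[-1] - m[-(k + 1L)]) /
        (sigma * sqrt(1 / len[-1] + 1 / len[-(k + 1L)]))
      if (min(zc) >= cfg$z_t) break
      bounds <- bounds[-which.min(zc)]
    }
    # refine: re-locate each surviving boundary to the SSE-optimal split of
    # its two flanking segments (greedy tree splits can be locally off)
    if (length(bounds)) {
      for (pass in 1:2) {
        ext <- c(0L, bounds, n)
        for (j in seq_along(bounds)) {
          lo <- ext[j] + 1L
          hi <- ext[j + 2L]
          if (hi - lo + 1L < 2L * cfg$min_bins) next
          splits <- (lo + cfg$min_bins - 1L):(hi - cfg$min_bins)
          nl <- splits - lo + 1L
          sl <- cs[splits + 1L] - cs[lo]
          ql <- cs2[splits + 1L] - cs2[lo]
          sser <- (cs2[hi + 1L] - cs2[splits + 1L]) -
            (cs[hi + 1L] - cs[splits + 1L])^2 / (hi - splits)
          ssel <- ql - sl^2 / nl
          bounds[j] <- splits[which.min(ssel + sser)]
          ext[j + 1L] <- bounds[j]
        }
        bounds <- sort(unique(bounds))
      }
    }
  }
  bounds <- sort(unique(bounds))
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  means <- vapply(seq_along(starts), function(i) {
    mean(ratios[starts[i]:ends[i]])
  }, numeric(1))
  out <- data.frame(start_bin = starts, end_bin = ends,
                    n_bins = ends - starts + 1L, mean = means,
                    mean_deviation = means - 1,
                    segment_z = abs(means - 1) * sqrt(ends - starts + 1L) / sigma,
                    stringsAsFactors = FALSE)
  attr(out, "sigma") <- sigma
  out
}

#' Exact minimal-SSE segmentation by dynamic programming
#'
#' Exhaustive changepoint search: among all partitions of `ratios` into `k`
#' contiguous segments (each at least `min_bins` long), returns the one with
#' the smallest total within-segment sum of squared errors. O(k n^2); the
#' exact counterpart of the recursive splitter for small instances.
#'
#' @param ratios Numeric vector.
#' @param k Number of segments.
#' @param min_bins Minimum segment length.
#' @return Data frame like [segment_ratios()] (without `segment_z`), plus
#'   attribute `sse` (the minimal total SSE).
#' @export
segment_exact <- function(ratios, k, min_bins = 1L) {
  n <- length(ratios)
  if (k < 1 || k > floor(n / min_bins)) stopf("infeasible segment count")
  cs <- c(0, cumsum(ratios))
  cs2 <- c(0, cumsum(ratios^2))
  sse <- function(lo, hi) {
    s <- cs[hi + 1L] - cs[lo]
    (cs2[hi + 1L] - cs2[lo]) - s^2 / (hi - lo + 1L)
  }
  # D[j, i]: minimal SSE of splitting 1..i into j segments
  D <- matrix(Inf, k, n)
  B <- matrix(NA_integer_, k, n)
  for (i in seq_len(n)) if (i >= min_bins) D[1, i] <- sse(1L, i)
  if (k > 1) {
    for (j in 2:k) {
      for (i in seq_len(n)) {
        if (i < j * min_bins) next
        prev <- (min_bins * (j - 1L)):(i - min_bins)
        cand <- D[j - 1L, prev] + vapply(prev, function(p) sse(p + 1L, i), numeric(1))
        w <- which.min(cand)
        D[j, i] <- cand[w]
        B[j, i] <- prev[w]
      }
    }
  }
  ends <- integer(k)
  ends[k] <- n
  if (k > 1) for (j in k:2) ends[j - 1L] <- B[j, ends[j]]
  starts <- c(1L, ends[-k] + 1L)
  means <- vapply(seq_len(k), function(i) mean(ratios[starts[i]:ends[i]]), numeric(1))
  out <- data.frame(start_bin = starts, end_bin = ends,
                    n_bins = ends - starts + 1L, mean = means,
                    mean_deviation = means - 1, stringsAsFactors = FALSE)
  attr(out, "sse") <- D[k, n]
  out
}

#' Convert retained segments into CNV calls
#'
#' Segments whose `segment_z` reaches the dynamic-threshold multiplier,
#' whose mean deviation clears the deviation floor, and which span at least
#' `min_bins` bins (but less than 90% of the chromosome — whole-chromosome
#' shifts belong to the aneuploidy caller) become duplication or deletion
#' calls, sized in Mb and attributed to a compartment of origin.
#'
#' @param segments A [segment_ratios()] result for one chromosome.
#' @param chrom Chromosome name.
#' @param bin_starts,bin_ends bp coordinates of the chromosome's bins.
#' @param ff Fetal fraction (`NA` gives indeterminate origin).
#' @param cfg A [segmentation_config()].
#' @return Data frame of class rows: `chromosome`, `start_bp`, `end_bp`,
#'   `size_mb`, `state` (`"dup"`/`"del"`), `mean_deviation`, `segment_z`,
#'   `origin`.
#' @export
call_cnvs <- function(segments, chrom, bin_starts, bin_ends, ff,
                      cfg = segmentation_config()) {
  sigma <- attr(segments, "sigma") %||% stats::sd(segments$mean)
  n_total <- sum(segments$n_bins)
  z_call <- call_threshold(cfg, n_total)
  keep <- segments$segment_z >= z_call &
    abs(segments$mean_deviation) >= cfg$dev_floor &
    segments$n_bins >= cfg$min_bins &
    segments$n_bins < 0.9 * n_total
  seg <- segments[keep, , drop = FALSE]
  if (!nrow(seg)) return(empty_cnv_calls())
  data.frame(chromosome = chrom,
             start_bp = bin_starts[seg$start_bin],
             end_bp = bin_ends[seg$end_bin],
             size_mb = (bin_ends[seg$end_bin] - bin_starts[seg$start_bin]) / 1e6,
             state = ifelse(seg$mean_deviation > 0, "dup", "del"),
             mean_deviation = seg$mean_deviation,
             segment_z = seg$segment_z,
             origin = vapply(seq_len(nrow(seg)), function(i) {
               infer_origin(seg$mean_deviation[i], ff,
                            sigma / sqrt(seg$n_bins[i]))
             }, character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Calling threshold with per-chromosome multiplicity control: the nominal
# level of the dynamic threshold (two-sided normal tail at z_t) is divided
# Bonferroni-style by the number of candidate segments the splitter can
# test (n_bins / min_bins), so a whole null chromosome produces a spurious
# call with probability ~2*(1 - pnorm(z_t)) — the same nominal rate as a
# whole-chromosome Z test. Without this, a per-segment 3 SD rule over ~80
# selected candidates yields several noise calls per genome.
call_threshold <- function(cfg, n_bins_chrom) {
  if (!isTRUE(cfg$multiplicity_adjust)) return(cfg$z_t)
  m <- max(1, floor(n_bins_chrom / cfg$min_bins))
  alpha <- 2 * stats::pnorm(-cfg$z_t) / m
  stats::qnorm(1 - alpha / 2)
}

empty_cnv_calls <- function() {
  data.frame(chromosome = character(0), start_bp = numeric(0),
              end_bp = numeric(0), size_mb = numeric(0), state = character(0),
              mean_deviation = numeric(0), segment_z = numeric(0),
              origin = character(0), stringsAsFactors = FALSE)
}

#' Attribute a CNV call to a fetal or maternal origin
#'
#' A heterozygous event confined to the fetal/placental compartment shifts
#' the corrected ratio by `ff/2`; a maternal heterozygous event shifts it by
#' `(1 - ff)/2` (not inherited) or `1/2` (inherited). The observed deviation
#' is classified to the nearest expectation; when the fetal and maternal
#' expectations are closer than twice the segment's standard error the call
#' is indeterminate, as is an exact tie.
#'
#' @param deviation Observed mean corrected-ratio deviation of the call.
#' @param ff Fetal fraction (`NA` gives `"indeterminate"`).
#' @param se Standard error of the segment mean (`sigma_hat / sqrt(L)`).
#' @return `"fetal"`, `"maternal"` or `"indeterminate"`.
#' @examples
#' infer_origin(0.05, ff = 0.10, se = 0.01)   # fetal
#' infer_origin(0.45, ff = 0.10, se = 0.01)   # maternal
#' @export
infer_origin <- function(deviation, ff, se) {
  if (is.na(ff)) return("indeterminate")
  e_fetal <- ff / 2
  e_maternal <- c((1 - ff) / 2, 1 / 2)
  if (abs(e_fetal - min(e_maternal)) < 2 * se) return("indeterminate")
  d <- abs(deviation)
  d_f <- abs(d - e_fetal)
  d_m <- min(abs(d - e_maternal))
  if (isTRUE(all.equal(d_f, d_m))) return("indeterminate")
  if (d_f < d_m) "fetal" else "maternal"
}

#' Genome-wide CNV calls for one normalised sample
#'
#' Runs [segment_ratios()] and [call_cnvs()] on every chromosome of a
#' normalised bin table except chrY, whose dosage is the province of the
#' chrY read-share (karyotype) logic rather than interval calling.
#'
#' @param bins A [normalize_bintable()] table.
#' @param ff Fetal fraction.
#' @param config A [run_config()].
#' @param x_baseline Expected chrX level for this sample (1 for a female
#'   fetus, `1 - ff/2` for a male); chrX ratios are rescaled by it so the
#'   sex-typical X dosage is not mistaken for a deletion.
#' @return Data frame of CNV calls (possibly zero rows).
#' @export
call_sample_cnvs <- function(bins, ff, config = run_config(), x_baseline = 1) {
  cfg <- config$segmentation
  chroms <- setdiff(unique(as.character(bins$chrom)), "chrY")
  out <- lapply(chroms, function(chr) {
    sub <- bins[bins$chrom == chr, , drop = FALSE]
    r <- sub$corrected_ratio
    if (chr == "chrX" && is.finite(x_baseline) && x_baseline > 0) {
      r <- r / x_baseline
    }
    seg <- segment_ratios(r, cfg)
    call_cnvs(seg, chr, sub$start, sub$end, ff, cfg)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_cnv_calls() else out
}
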