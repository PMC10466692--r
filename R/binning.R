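#' Build equal-read genome windows
#'
#' Partitions the genome into `n_windows` windows that each carry (as close
#' as the fine-bin resolution allows) the same expected read mass, never
#' spanning a chromosome boundary. Windows are allocated to chromosomes in
#' proportion to their expected mass (largest-remainder rounding, at least
#' one window each) and window boundaries within a chromosome are the
#' cumulative-mass quantile cuts of the fine bins.
#'
#' @param reference_counts Data frame with columns `chrom`, `start`, `end`
#'   and `expected` (fine-bin expected reads).
#' @param n_windows Number of windows; must be at least the number of
#'   chromosomes and at most the number of fine bins.
#' @return Data frame with columns `chrom`, `start`, `end`, `n_fine`
#'   (fine bins merged) and `expected` (window mass).
#' @export
make_windows <- function(reference_counts, n_windows) {
  req <- c("chrom", "start", "end", "expected")
  if (!all(req %in% names(reference_counts))) {
    stopf("`reference_counts` needs columns %s", paste(req, collapse = ", "))
  }
  rc <- reference_counts
  chroms <- unique(rc$chrom)
  if (n_windows < length(chroms)) stopf("`n_windows` must be >= number of chromosomes")
  if (n_windows > nrow(rc)) stopf("`n_windows` exceeds the number of fine bins")
  total <- sum(rc$expected)
  if (total <= 0) stopf("total expected reads must be > 0")

  mass <- tapply(rc$expected, rc$chrom, sum)[chroms]
  # largest-remainder allocation with a floor of one window per chromosome
  ideal <- n_windows * mass / total
  k <- pmax(1L, floor(ideal))
  excess <- sum(k) - n_windows
  if (excess > 0) {  # floor of 1 overshot: trim where the rounding gain is largest
    ord <- order(k - ideal, decreasing = TRUE)
    i <- 1L
    while (excess > 0 && i <= length(ord)) {
      j <- ord[i]
      if (k[j] > 1L) { k[j] <- k[j] - 1L; excess <- excess - 1L }
      i <- if (i == length(ord)) 1L else i + 1L
    }
  } else if (excess < 0) {
    rem <- ideal - floor(ideal)
    ord <- order(rem, decreasing = TRUE)
    add <- ord[seq_len(-excess)]
    k[add] <- k[add] + 1L
  }
  # cap at the fine-bin count per chromosome
  nb <- tapply(rc$expected, rc$chrom, length)[chroms]
  over <- k > nb
  while (any(over)) {
    spare <- sum(k[over] - nb[over])
    k[over] <- nb[over]
    room <- which(k < nb)
    room <- room[order(ideal[room] - k[room], decreasing = TRUE)]
    for (j in room) {
      if (spare == 0) break
      k[j] <- k[j] + 1L
      spare <- spare - 1L
    }
    over <- k > nb
    if (spare == 0 && !any(over)) break
  }

  out <- lapply(seq_along(chroms), function(ci) {
    sub <- rc[rc$chrom == chroms[ci], , drop = FALSE]
    kk <- k[ci]
    if (kk == 1L) {
      return(data.frame(chrom = chroms[ci], start = min(sub$start),
                        end = max(sub$end), n_fine = nrow(sub),
                        expected = sum(sub$expected), stringsAsFactors = FALSE))
    }
    cum <- cumsum(sub$expected)
    targets <- cum[length(cum)] * seq_len(kk - 1) / kk
    cuts <- findInterval(targets, cum, left.open = TRUE) + 1L
    cuts <- pmin(pmax(cuts, seq_len(kk - 1) + 0L), nrow(sub) - (kk - 1):1)
    cuts <- cummax(cuts)  # keep boundaries ordered
    bounds <- c(0L, cuts, nrow(sub))
    data.frame(chrom = chroms[ci],
               start = sub$start[bounds[-length(bounds)] + 1L],
               end = sub$end[bounds[-1L]],
               n_fine = diff(bounds),
               expected = vapply(seq_len(kk), function(w) {
                 sum(sub$expected[(bounds[w] + 1L):bounds[w + 1L]])
               }, numeric(1)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Relative read numbers
#'
#' The screening signal of each window: its read count divided by the mean
#' count over all windows, so the genome-wide mean is exactly 1.
#'
#' @param raw_counts Numeric vector of window read counts.
#' @return Numeric vector of ratios with `mean(.) == 1`.
#' @examples
#' relative_reads(c(10, 20, 30))
#' @export
relative_reads <- function(raw_counts) {
  if (!is.numeric(raw_counts) || length(raw_counts) == 0) {
    stopf("`raw_counts` must be a non-empty numeric vector")
  }
  m <- mean(raw_counts)
  if (m <= 0) stopf("mean read count must be > 0 (all-zero input rejected)")
  raw_counts / m
}

#' Least-squares fit of GC content against relative reads
#'
#' Ordinary least squares of the relative read number on the window GC
#' fraction — the linear GC-bias model removed by [correct_gc()].
#'
#' @param gc Window GC fractions.
#' @param r Relative read numbers (same length, at least 3).
#' @return A list of class `gc_fit`: `intercept`, `slope`, `residual_sd`,
#'   `constant_gc` (flag: degenerate input, identity fit returned).
#' @export
fit_gc <- function(gc, r) {
  if (length(gc) != length(r)) stopf("`gc` and `r` must have equal length")
  if (length(gc) < 3) stopf("need at least 3 windows to fit the GC model")
  vg <- stats::var(gc)
  if (vg < .Machine$double.eps) {
    res <- r - mean(r)
    return(structure(list(intercept = mean(r), slope = 0,
                          residual_sd = stats::sd(res), constant_gc = TRUE),
                     class = "gc_fit"))
  }
  slope <- stats::cov(gc, r) / vg
  intercept <- mean(r) - slope * mean(gc)
  res <- r - (intercept + slope * gc)
  structure(list(intercept = intercept, slope = slope,
                 residual_sd = stats::sd(res), constant_gc = FALSE),
            class = "gc_fit")
}

predict_gc <- function(fit, gc) fit$intercept + fit$slope * gc

#' Remove the linear GC effect from a bin table
#'
#' Divides each window's relative read number by its fitted GC value and
#' renormalises to mean 1. The first pass uses the supplied fit; the
#' correction is then iterated (refit, divide, renormalise) until the OLS
#' slope of the corrected ratio on GC is below `tol`, which makes the
#' correction idempotent.
#'
#' @param bins Data frame with columns `gc` and `relative_reads` (e.g. from
#'   [normalize_bintable()] internals).
#' @param fit A [fit_gc()] result for the same sample.
#' @param tol Convergence tolerance on the residual GC slope.
#' @param max_iter Iteration cap.
#' @param eps Positivity floor for fitted values; bins clamped at the floor
#'   are flagged in the `clamped_bins` attribute.
#' @return `bins` with a `corrected_ratio` column (`mean == 1`); attributes
#'   `gc_fit` (the supplied fit) and `clamped_bins`.
#' @export
correct_gc <- function(bins, fit, tol = 1e-8, max_iter = 25L, eps = 1e-6) {
  stopifnot(inherits(fit, "gc_fit"))
  if (!all(c("gc", "relative_reads") %in% names(bins))) {
    stopf("`bins` needs columns gc and relative_reads")
  }
  x <- bins$relative_reads
  clamped <- logical(length(x))
  f <- predict_gc(fit, bins$gc)
  for (it in seq_len(max_iter)) {
    low <- f < eps
    clamped <- clamped | low
    f[low] <- eps
    x <- x / f
    x <- x / mean(x)
    nxt <- fit_gc(bins$gc, x)
    if (abs(nxt$slope) < tol || nxt$constant_gc) break
    f <- predict_gc(nxt, bins$gc)
  }
  bins$corrected_ratio <- x
  attr(bins, "gc_fit") <- fit
  attr(bins, "clamped_bins") <- which(clamped)
  bins
}

#' Normalise a raw bin table
#'
#' The full normalisation front-end: computes relative read numbers, fits
#' the linear GC model and removes it, yielding the corrected ratios every
#' caller consumes.
#'
#' @param bins Data frame with columns `chrom`, `start`, `end`, `gc`,
#'   `raw_count`.
#' @return `bins` with `relative_reads` and `corrected_ratio` columns and a
#'   `gc_fit` attribute.
#' @examples
#' g <- synthetic_genome()
#' s <- simulate_sample(sim_sample_spec(seed = 3), g)
#' b <- normalize_bintable(s$bins)
#' mean(b$corrected_ratio)
#' @export
normalize_bintable <- function(bins) {
  req <- c("chrom", "start", "end", "gc", "raw_count")
  if (!all(req %in% names(bins))) {
    stopf("bin table needs columns %s", paste(req, collapse = ", "))
  }
  bins$relative_reads <- relative_reads(bins$raw_count)
  fit <- fit_gc(bins$gc, bins$relative_reads)
  correct_gc(bins, fit)
}
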