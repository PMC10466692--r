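test_that("segmentation handles constant signal and clean changepoints", {
  cfg <- segmentation_config()
  expect_equal(nrow(segment_ratios(rep(1, 100), cfg)), 1)
  # one step of +0.10 over 50 of 200 bins, noise SD 0.01: both breakpoints
  # recovered within one bin
  x <- step_signal(200, c(80, 130), c(1, 1.10, 1), sd = 0.01, seed = 12)
  seg <- segment_ratios(x, cfg)
  expect_equal(nrow(seg), 3)
  expect_lte(abs(seg$end_bin[1] - 80), 1)
  expect_lte(abs(seg$end_bin[2] - 130), 1)
  expect_equal(seg$mean_deviation[2], 0.10, tolerance = 0.02)
  expect_error(segment_ratios(numeric(0)), "no bins")
})

test_that("exact DP segmentation matches brute-force enumeration at tiny n", {
  sse_of <- function(x, bounds) {
    starts <- c(1L, bounds + 1L)
    ends <- c(bounds, length(x))
    sum(vapply(seq_along(starts), function(i) {
      seg <- x[starts[i]:ends[i]]
      sum((seg - mean(seg))^2)
    }, numeric(1)))
  }
  with_seed(31, {
    for (rep in 1:25) {
      n <- sample(6:12, 1)
      k <- sample(1:3, 1)
      x <- stats::rnorm(n)
      dp <- segment_exact(x, k, min_bins = 1)
      # enumerate all placements of k-1 boundaries
      best <- Inf
      if (k == 1) {
        best <- sse_of(x, integer(0))
      } else {
        combos <- utils::combn(n - 1, k - 1)
        for (j in seq_len(ncol(combos))) {
          best <- min(best, sse_of(x, combos[, j]))
        }
      }
      expect_equal(attr(dp, "sse"), best, tolerance = 1e-9)
    }
  })
})

test_that("recursive segmentation matches the exhaustive DP oracle", {
  cfg <- segmentation_config()
  agree <- vapply(1:30, function(rep) {
    with_seed(500 + rep, {
      n <- sample(80:200, 1)
      k_true <- sample(0:3, 1)
      bounds <- if (k_true == 0) integer(0) else {
        sort(sample(seq(15, n - 15, by = 1), k_true))
      }
      # enforce min segment spacing
      while (length(bounds) > 1 && min(diff(bounds)) < 15) {
        bounds <- sort(sample(seq(15, n - 15), k_true))
      }
      means <- 1 + cumsum(c(0, sample(c(-1, 1), length(bounds),
                                      replace = TRUE) * stats::runif(length(bounds), 0.3, 0.6)))
      x <- step_signal(n, bounds, means, sd = 0.05, seed = 900 + rep)
      seg <- segment_ratios(x, cfg)
      dp <- segment_exact(x, nrow(seg), min_bins = cfg$min_bins)
      identical(seg$end_bin, dp$end_bin)
    })
  }, logical(1))
  expect_gte(mean(agree), 0.97)
})

test_that("breakpoints are invariant to rescaling all ratios", {
  x <- step_signal(150, c(60, 100), c(1, 1.4, 1), sd = 0.05, seed = 21)
  s1 <- segment_ratios(x)
  s2 <- segment_ratios(1.7 * x)
  expect_equal(s1$end_bin, s2$end_bin)
})

test_that("segments become calls only past the dynamic threshold and floors", {
  cfg <- segmentation_config()
  x <- step_signal(200, c(80, 130), c(1, 0.90, 1), sd = 0.02, seed = 3)
  seg <- segment_ratios(x, cfg)
  starts <- (0:199) * 5e4
  calls <- call_cnvs(seg, "chr2", starts, starts + 5e4, ff = 0.2, cfg)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$state, "del")
  expect_equal(calls$size_mb, 2.5)
  expect_equal(calls$origin, "fetal")
  # constant signal: no calls
  seg0 <- segment_ratios(rep(1, 200) + step_signal(200, integer(0), 0, 0.02, 4), cfg)
  expect_equal(nrow(call_cnvs(seg0, "chr2", starts, starts + 5e4, 0.2, cfg)), 0)
  # a whole-chromosome shift is not a CNV call
  segw <- segment_ratios(step_signal(200, integer(0), 1.1, 0.02, 5), cfg)
  expect_equal(nrow(call_cnvs(segw, "chr2", starts, starts + 5e4, 0.2, cfg)), 0)
})

test_that("origin attribution classifies to the nearest mixture expectation", {
  expect_equal(infer_origin(0.05, ff = 0.10, se = 0.01), "fetal")
  expect_equal(infer_origin(0.45, ff = 0.10, se = 0.01), "maternal")
  expect_equal(infer_origin(-0.5, ff = 0.10, se = 0.01), "maternal")
  # midway between the fetal (0.05) and maternal (0.45) expectations
  expect_equal(infer_origin(0.25, ff = 0.10, se = 0.01), "indeterminate")
  # expectations closer than twice the standard error
  expect_equal(infer_origin(0.3, ff = 0.45, se = 0.2), "indeterminate")
  expect_equal(infer_origin(0.3, ff = NA, se = 0.01), "indeterminate")
})

test_that("fetal CNV recovery improves with size and maternal events are easy", {
  g <- test_genome()
  cfg <- test_config()
  detect <- function(scen, sz, ff, seed) {
    sp <- scenario_sample_spec(scen, "c", g, ff = ff, cnv_size_mb = sz,
                               cnv_state = "del", chromosome = "chr2",
                               seed = seed)
    s <- simulate_sample(sp, g)
    calls <- call_sample_cnvs(normalize_bintable(s$bins), ff, cfg)
    ev <- if (scen == "maternal_cnv_uninherited") sp$maternal_events[[1]] else sp$fetal_events[[1]]
    any(calls$chromosome == "chr2" & calls$state == "del" &
          pmin(calls$end_bp, ev$end) - pmax(calls$start_bp, ev$start) >
            0.5 * (ev$end - ev$start))
  }
  small <- mean(vapply(1:12, function(i) detect("fetal_cnv", 0.8, 0.08, 6000 + i), logical(1)))
  large <- mean(vapply(1:12, function(i) detect("fetal_cnv", 7.5, 0.10, 6100 + i), logical(1)))
  expect_lt(small, 0.5)     # sub-Mb fetal events are frequently missed
  expect_gt(large, small)
  # maternal-origin events are detected at near-ceiling rate at low and
  # moderate ff alike (deviation ~0.5 regardless)
  m_lo <- mean(vapply(1:10, function(i) detect("maternal_cnv_uninherited", 1.5, 0.05, 6200 + i), logical(1)))
  m_hi <- mean(vapply(1:10, function(i) detect("maternal_cnv_uninherited", 1.5, 0.25, 6300 + i), logical(1)))
  expect_gte(m_lo, 0.8)
  expect_gte(m_hi, 0.8)
})

test_that("a euploid genome carries a few sub-Mb noise calls at the default threshold", {
  g <- test_genome()
  cfg <- test_config()
  n_calls <- vapply(1:10, function(i) {
    s <- simulate_sample(sim_sample_spec(sample_id = i, fetal_fraction = 0.2,
                                         fetal_sex = "female",
                                         seed = 8800L + i), g)
    calls <- call_sample_cnvs(normalize_bintable(s$bins), 0.2, cfg)
    nrow(calls)
  }, numeric(1))
  # the documented scan-statistic behaviour of an unadjusted per-segment
  # 3-SD rule over ~3,000 windows: some spurious calls, but bounded
  expect_gt(mean(n_calls), 0.5)
  expect_lt(mean(n_calls), 15)
  # the multiplicity-adjusted mode suppresses most of them
  cfg2 <- run_config(segmentation = segmentation_config(multiplicity_adjust = TRUE))
  n_adj <- vapply(1:10, function(i) {
    s <- simulate_sample(sim_sample_spec(sample_id = i, fetal_fraction = 0.2,
                                         fetal_sex = "female",
                                         seed = 8800L + i), g)
    nrow(call_sample_cnvs(normalize_bintable(s$bins), 0.2, cfg2))
  }, numeric(1))
  expect_lt(mean(n_adj), mean(n_calls))
})
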