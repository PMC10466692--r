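iscn_strings <- function() {
  readLines(cfscreen_fixture("iscn_result_strings.txt"), encoding = "UTF-8")
}

test_that("the ISCN dialect parses, including mosaic ranges and typos", {
  f <- parse_iscn("arr[GRCh37] 21q11.2q22.3(15,016,486_48,093,361)×3")
  expect_equal(f$chrom, "chr21")
  expect_equal(f$start, 15016485)   # printed 1-based -> 0-based half-open
  expect_equal(f$end, 48093361)
  expect_equal(f$cn_low, 3L)
  expect_equal(f$category, "T21")   # spans >=90% of the callable length
  # mosaic copy-number range with an en dash
  f2 <- parse_iscn("arr[GRCh37] 21q21.3q22.3(28,054,301_48,093,361)×2–3")
  expect_true(f2$mosaic)
  expect_equal(c(f2$cn_low, f2$cn_high), c(2L, 3L))
  # whole-chromosome X loss -> 45,X
  f3 <- parse_iscn("arr[GRCh37] Xp22.33q28(168,551_155,233,098)×1")
  expect_equal(f3$category, "SCA")
  expect_equal(f3$karyotype, "45,X")
  # karyotype tokens
  expect_equal(parse_iscn("45,XO")$karyotype, "45,X")
  expect_equal(parse_iscn("47,XYY")$karyotype, "47,XYY")
  expect_equal(parse_iscn("T16")$category, "RAT_chr16")
  # whole-chromosome mosaic trisomy 20 classifies as a rare trisomy
  f4 <- parse_iscn("arr[GRCh37]20p13q13.33(61,661_62,913,645)×2–3")
  expect_equal(f4$category, "RAT_chr20")
  # malformed strings name the offending token
  expect_error(parse_iscn("arr[GRCh38] 21q11(1_2)×3"), "malformed")
  expect_error(parse_iscn("arr[GRCh37] 21q11(5_2)×3"), "start")
  expect_error(parse_iscn("46,Xq"), "malformed")
})

test_that("every transcribed result string parses and round-trips", {
  for (s in iscn_strings()) {
    f <- parse_iscn(s)
    expect_s3_class(f, "data.frame")
    once <- format_iscn(f)
    twice <- format_iscn(parse_iscn(once))
    expect_identical(once, twice)
    back <- parse_iscn(once)
    expect_equal(back$start, f$start)
    expect_equal(back$end, f$end)
    expect_equal(back$cn_low, f$cn_low)
    expect_equal(back$cn_high, f$cn_high)
  }
})

test_that("finding sizes equal the printed-coordinate differences", {
  f <- parse_iscn("arr[GRCh37] 21q11.2q22.3(15,016,486_48,093,361)×3")
  expect_equal(finding_size_mb(f), 33.076875)
  f2 <- parse_iscn("arr[GRCh37]Yp11.2q11.23(5,997,807_28,799,653)×0")
  expect_equal(finding_size_mb(f2), 22.801846)
  # karyotype-level findings have no interval size
  expect_true(is.na(finding_size_mb(parse_iscn("45,XO"))))
})

test_that("call matching classifies TP/FP/FN and conserves counts", {
  mk_screen <- function(aneu = NULL, sca = "none", cnv = NULL) {
    structure(list(sample_id = "s",
                   aneuploidy_calls = aneu %||% data.frame(
                     chromosome = character(0), z = numeric(0),
                     call = character(0)),
                   sca_karyotype = sca,
                   cnv_calls = cnv %||% empty_cnv_calls()),
              class = "screening_calls")
  }
  t21_screen <- mk_screen(data.frame(chromosome = "chr21", z = 8, call = "trisomy"))
  t21_dx <- diagnostic_finding_set(list(
    diagnostic_finding("chr21", 14300000, 48129895, 3)))
  mc <- match_calls(t21_screen, t21_dx)
  expect_equal(mc$class[mc$category == "T21"], "TP")
  # the discordant sex-chromosome pattern: screening 45,X vs diagnostic XYY
  mc2 <- match_calls(mk_screen(sca = "45,X"),
                     diagnostic_finding_set(list(
                       diagnostic_finding("chrY", 0, 59373566, 2,
                                          karyotype = "47,XYY"))))
  expect_setequal(mc2$class[mc2$category == "SCA"], c("FP", "FN"))
  # CNV inside a larger diagnostic of the same sign at ~30% reciprocal overlap
  cnv_call <- data.frame(chromosome = "chr5", start_bp = 10e6, end_bp = 13e6,
                         size_mb = 3, state = "del", mean_deviation = -0.4,
                         segment_z = 9, origin = "maternal")
  big_dx <- diagnostic_finding_set(list(
    diagnostic_finding("chr5", 9e6, 19e6, 1)))
  mc3 <- match_calls(mk_screen(cnv = cnv_call), big_dx, overlap = 0.25)
  expect_equal(mc3$class[mc3$category == "CNV"], "TP")
  # same pair fails a stricter overlap rule
  mc3b <- match_calls(mk_screen(cnv = cnv_call), big_dx, overlap = 0.5)
  expect_setequal(mc3b$class[mc3b$category == "CNV"], c("FP", "FN"))
  # sub-floor diagnostic findings are excluded, not counted as FN
  small_dx <- diagnostic_finding_set(list(
    diagnostic_finding("chr5", 10e6, 10.3e6, 1)))
  mc4 <- match_calls(mk_screen(), small_dx)
  expect_false(any(mc4$category == "CNV" & mc4$class == "FN"))
  # ROH findings are never screenable
  roh_dx <- diagnostic_finding_set(list(
    diagnostic_finding("chr16", 1e6, 30e6, 2, roh = TRUE)))
  mc5 <- match_calls(mk_screen(), roh_dx)
  expect_equal(mc5$class[mc5$category == "ROH"], "NS")
  # both empty -> true negatives everywhere
  mc6 <- match_calls(mk_screen(), diagnostic_finding_set())
  expect_true(all(mc6$class == "TN"))
})

test_that("classification counts are conserved across a simulated batch", {
  cls <- lapply(1:6, function(i) {
    sc <- screen_scenario(c("t21", "euploid", "cpm_t21")[(i %% 3) + 1],
                          seed = 7000L + i)
    match_calls(sc$calls, sc$diagnostic)
  })
  agg <- aggregate_classifications(cls)
  all_rows <- do.call(rbind, cls)
  for (cat in agg$category) {
    expect_equal(agg$tp[agg$category == cat] + agg$fn[agg$category == cat],
                 sum(all_rows$category == cat & all_rows$class %in% c("TP", "FN")))
    expect_equal(agg$tp[agg$category == cat] + agg$fp[agg$category == cat],
                 sum(all_rows$category == cat & all_rows$class %in% c("TP", "FP")))
  }
})

test_that("metric rows compute the published rates and valid intervals", {
  expect_equal(compute_metrics("T21", 31, 28, 29, 28)$sensitivity,
               100 * 28 / 29, tolerance = 1e-9)
  expect_equal(round(compute_metrics("T21", 31, 28)$ppv, 2), 90.32)
  expect_equal(round(compute_metrics("overall", n_diagnostic_positive = 86,
                                     n_detected = 83)$sensitivity, 2), 96.51)
  expect_equal(compute_metrics("RAT", 8, 4)$ppv, 50)
  r <- compute_metrics("x", 31, 28, 29, 28)
  expect_equal(r$miss_rate, 100 - r$sensitivity)
  expect_true(r$ci_low >= 0 && r$ci_high <= 100)
  expect_true(r$ci_low <= r$sensitivity && r$sensitivity <= r$ci_high)
  # intervals shrink with n at the same rate
  wide <- compute_metrics("a", n_diagnostic_positive = 10, n_detected = 9)
  narrow <- compute_metrics("b", n_diagnostic_positive = 1000, n_detected = 900)
  expect_lt(narrow$ci_high - narrow$ci_low, wide$ci_high - wide$ci_low)
  # zero denominator flagged, not crashed
  z <- compute_metrics("none", n_diagnostic_positive = 0, n_detected = 0)
  expect_true(z$undefined)
  expect_true(is.na(z$sensitivity))
})

test_that("Wilson intervals agree with independent score-test inversions", {
  # plain Wilson: equals the uncorrected score interval prop.test computes
  for (case in list(c(28, 29), c(4, 8), c(18, 20), c(144, 234))) {
    ours <- wilson_ci(case[1], case[2], method = "wilson")
    ref <- suppressWarnings(
      stats::prop.test(case[1], case[2], correct = FALSE)$conf.int)
    expect_equal(ours, as.numeric(ref), tolerance = 1e-9)
  }
  # continuity-corrected Wilson: equals the numeric inversion of the
  # continuity-corrected score test |p_hat - p| - 1/(2n) = z * sqrt(pq/n)
  z <- stats::qnorm(0.975)
  for (case in list(c(28, 29), c(4, 8), c(144, 234))) {
    x <- case[1]; n <- case[2]; p_hat <- x / n
    f <- function(p) (abs(p_hat - p) - 1 / (2 * n)) - z * sqrt(p * (1 - p) / n)
    lo <- stats::uniroot(f, c(1e-9, p_hat), tol = 1e-12)$root
    hi <- stats::uniroot(f, c(p_hat, 1 - 1e-9), tol = 1e-12)$root
    expect_equal(wilson_ci(x, n, method = "wilson_cc"), c(lo, hi),
                 tolerance = 1e-6)
  }
  expect_equal(wilson_ci(0, 10)[1], 0)
  expect_equal(wilson_ci(10, 10)[2], 1)
})

test_that("size strata follow the reporting boundaries", {
  labs <- cnv_strata_labels()
  expect_equal(stratify_cnv(1.0), labs[1])    # 1 Mb belongs to the first band
  expect_equal(stratify_cnv(10.0), labs[6])   # 10 Mb belongs to the top band
  expect_equal(stratify_cnv(c(0.5, 2, 3, 5, 9.99)),
               labs[c(1, 2, 3, 4, 5)])
  expect_true(is.na(stratify_cnv(0.4)))       # below the selection floor
})

test_that("syndrome annotation matches region, sign and coverage", {
  dg <- diagnostic_finding("chr22", 18900000, 21500000, 1)
  expect_equal(annotate_syndrome(dg), "DiGeorge (22q11.2)")
  rcad <- diagnostic_finding("chr17", 34800000, 36250000, 1)
  expect_equal(annotate_syndrome(rcad), "RCAD (17q12)")
  # sign mismatch: a duplication of the DiGeorge region is not the syndrome
  dg_dup <- diagnostic_finding("chr22", 18900000, 21500000, 3)
  expect_true(is.na(annotate_syndrome(dg_dup)))
  # random duplication elsewhere
  expect_true(is.na(annotate_syndrome(diagnostic_finding("chr2", 5e6, 9e6, 3))))
  # insufficient coverage of the canonical region
  half <- diagnostic_finding("chr22", 18900000, 19500000, 1)
  expect_true(is.na(annotate_syndrome(half)))
})

test_that("fixture reports reproduce the packaged tables and empty input is safe", {
  fx <- read_fixture(cfscreen_fixture("aneuploidy_ppv_counts.tsv"))
  rep3 <- build_report(fixture = fx)
  expect_equal(round(rep3$metrics$ppv, 2), c(90.32, 87.50, 25.00, 88.89, 50.00))
  empty <- build_report(pairs = list(match_calls(
    structure(list(sample_id = "e",
                   aneuploidy_calls = data.frame(chromosome = character(0),
                                                 z = numeric(0),
                                                 call = character(0)),
                   sca_karyotype = "none", cnv_calls = empty_cnv_calls()),
              class = "screening_calls"),
    diagnostic_finding_set())))
  expect_s3_class(empty$metrics, "data.frame")
  expect_error(build_report(), "exactly one")
})
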