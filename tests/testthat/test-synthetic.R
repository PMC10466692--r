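test_that("synthetic genome tiles chromosomes with valid GC", {
  g <- test_genome()
  expect_setequal(unique(g$chrom), names(grch37_lengths))
  expect_true(all(g$gc >= 0 & g$gc <= 1))
  # bins tile each chromosome without gaps or overlap
  for (chr in c("chr1", "chr21", "chrX")) {
    sub <- g[g$chrom == chr, ]
    expect_equal(sub$start[-1], sub$end[-nrow(sub)])
  }
  # deterministic given seed, different under another seed
  expect_identical(synthetic_genome(seed = 7)$gc, synthetic_genome(seed = 7)$gc)
  expect_false(identical(synthetic_genome(seed = 7)$gc,
                         synthetic_genome(seed = 8)$gc))
  # relative chromosome sizes preserved (chr1 ~5x chr21)
  n21 <- sum(g$chrom == "chr21")
  n1 <- sum(g$chrom == "chr1")
  expect_equal(n1 / n21, grch37_lengths[["chr1"]] / grch37_lengths[["chr21"]],
               tolerance = 0.05)
})

test_that("expected intensities conserve depth and obey the mixture formula", {
  g <- test_genome()
  # identity case: no fetal fraction, no events -> unit plasma ratio
  # everywhere except chrY (maternal genome carries no Y)
  em0 <- expected_bin_means(sim_sample_spec(fetal_fraction = 0), g)
  expect_true(all(em0$plasma_ratio[g$chrom != "chrY"] == 1))
  expect_true(all(em0$plasma_ratio[g$chrom == "chrY"] == 0))
  expect_equal(sum(em0$mu), 8.5e6, tolerance = 1e-12)

  # maternal het duplication not inherited by the fetus, ff = 0.10:
  # (1 - 0.10) * 3/2 + 0.10 * 2/2 = 1.45
  ev <- genomic_event("chr4", 1e6, 3e6, copy_number = 3)
  em <- expected_bin_means(
    sim_sample_spec(fetal_fraction = 0.10, maternal_events = list(ev)), g)
  idx <- g$chrom == "chr4" & g$start >= 1e6 & g$end <= 3e6
  expect_equal(unique(em$plasma_ratio[idx]), 1.45)
  expect_equal(sum(em$mu), 8.5e6, tolerance = 1e-6)

  # placental mosaic fraction scales the placental term
  sp <- sim_sample_spec(fetal_fraction = 0.2,
                        placental_events = list(genomic_event("chr21", copy_number = 3)),
                        placental_mosaic_fraction = 0.5)
  em2 <- expected_bin_means(sp, g)
  expect_equal(unique(em2$plasma_ratio[g$chrom == "chr21"]),
               (1 - 0.2) + 0.2 * ((1 - 0.5) * 2 + 0.5 * 3) / 2)
})

test_that("empirical corrected chr21 ratio matches the closed form for T21", {
  g <- test_genome()
  sp_base <- scenario_sample_spec("t21", "t", g, ff = 0.20, seed = 1L)
  em <- expected_bin_means(sp_base, g)
  # closed form including the genome-wide renormalisation of corrected ratios
  expected <- mean(em$plasma_ratio[g$chrom == "chr21"]) / mean(em$plasma_ratio)
  expect_equal(expected, 1.10 / mean(em$plasma_ratio), tolerance = 1e-12)
  reps <- vapply(1:200, function(i) {
    sp <- scenario_sample_spec("t21", "t", g, ff = 0.20, seed = 5000L + i)
    b <- normalize_bintable(simulate_sample(sp, g)$bins)
    mean(b$corrected_ratio[b$chrom == "chr21"])
  }, numeric(1))
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - expected), 3 * se + 1e-4)
})

test_that("identical spec and seed give bit-identical output", {
  g <- test_genome()
  sp <- sim_sample_spec(fetal_fraction = 0.13, fetal_sex = "male", seed = 99L)
  s1 <- simulate_sample(sp, g)
  s2 <- simulate_sample(sp, g)
  expect_identical(s1$bins, s2$bins)
  expect_identical(s1$profile, s2$profile)
  c1 <- simulate_cohort(5, c(t21 = 0.5), seed = 11L, genome = g)
  c2 <- simulate_cohort(5, c(t21 = 0.5), seed = 11L, genome = g)
  expect_identical(lapply(c1, `[[`, "bins"), lapply(c2, `[[`, "bins"))
})

test_that("compartments are separated: placenta drives plasma, fetus drives truth", {
  g <- test_genome()
  tri <- genomic_event("chr21", copy_number = 3)
  # placental-only event: plasma shifted, diagnostic truth normal
  cpm <- simulate_sample(sim_sample_spec(fetal_fraction = 0.2,
                                         placental_events = list(tri),
                                         seed = 5L), g)
  expect_equal(nrow(truth_to_diagnostic(cpm$truth, g)), 0)
  em_cpm <- expected_bin_means(sim_sample_spec(fetal_fraction = 0.2,
                                               placental_events = list(tri)), g)
  expect_gt(mean(em_cpm$plasma_ratio[g$chrom == "chr21"]), 1.05)
  # fetal-only event: plasma expectations unchanged, truth positive
  suppressWarnings({
    em_fet <- expected_bin_means(sim_sample_spec(fetal_fraction = 0.2,
                                                 fetal_events = list(tri)), g)
  })
  expect_true(all(em_fet$plasma_ratio[g$chrom == "chr21"] == 1))
  fet <- simulate_sample(sim_sample_spec(fetal_fraction = 0.2,
                                         fetal_events = list(tri), seed = 6L), g)
  dx <- truth_to_diagnostic(fet$truth, g)
  expect_equal(dx$category, "T21")
})

test_that("cohort scenario counts are binomial and prevalences respected", {
  g <- test_genome()
  co <- simulate_cohort(200, c(t21 = 0.5), seed = 21L, genome = g)
  n_t21 <- sum(vapply(co, `[[`, character(1), "scenario") == "t21")
  # Binomial(200, 0.5): mean 100, sd ~7.1
  expect_gt(n_t21, 100 - 4 * 7.1)
  expect_lt(n_t21, 100 + 4 * 7.1)
  expect_error(simulate_cohort(0, c(t21 = 1), seed = 1), "positive")
  expect_error(simulate_cohort(10, c(t21 = 0.7, euploid = 0.5), seed = 1),
               "sum")
})

test_that("diagnostic rendering applies mosaic and size reporting rules", {
  g <- test_genome()
  lens <- genome_chrom_lengths(g)
  mk_truth <- function(events, fracs) {
    simulate_sample(sim_sample_spec(fetal_fraction = 0.2,
                                    fetal_events = events,
                                    placental_events = events,
                                    fetal_mosaic_fraction = fracs,
                                    placental_mosaic_fraction = fracs,
                                    seed = 3L), g)$truth
  }
  # full trisomy -> one x3 whole-chromosome finding
  dx <- truth_to_diagnostic(mk_truth(list(genomic_event("chr21", copy_number = 3)), 1), g)
  expect_equal(nrow(dx), 1)
  expect_equal(dx$cn_low, 3L)
  expect_equal(dx$end - dx$start, unname(lens[["chr21"]]))
  # 1.2 Mb deletion -> x1 interval of ~1.2 Mb
  del <- genomic_event("chr3", 2e6, 3.2e6, copy_number = 1)
  dx2 <- truth_to_diagnostic(mk_truth(list(del), 1), g)
  expect_equal(dx2$cn_low, 1L)
  expect_equal(finding_size_mb(dx2[1, ]), 1.2, tolerance = 1e-5)
  # mosaic fraction 0.14 -> x2-3 range, flagged mosaic, parser round-trip
  dx3 <- truth_to_diagnostic(mk_truth(list(genomic_event("chr21", copy_number = 3)), 0.14), g)
  expect_true(dx3$mosaic)
  expect_equal(c(dx3$cn_low, dx3$cn_high), c(2L, 3L))
  rt <- parse_iscn(dx3$raw)
  expect_equal(c(rt$cn_low, rt$cn_high, rt$mosaic), c(2L, 3L, TRUE))
  # below 0.1 mosaic fraction rounds to the majority (normal) genotype
  dx4 <- truth_to_diagnostic(mk_truth(list(genomic_event("chr21", copy_number = 3)), 0.05), g)
  expect_equal(nrow(dx4), 0)
  # interval below the reporting threshold is suppressed
  tiny <- genomic_event("chr3", 2e6, 2.05e6, copy_number = 1)
  expect_equal(nrow(truth_to_diagnostic(mk_truth(list(tiny), 1), g)), 0)
})

test_that("fragment short-fraction increases with the fetal share", {
  g <- test_genome()
  p <- vapply(c(0.05, 0.2, 0.5), function(ff) {
    em <- expected_bin_means(sim_sample_spec(fetal_fraction = ff), g)
    mean(em$p_short[g$chrom != "chrY"])
  }, numeric(1))
  expect_true(all(diff(p) > 0))
  s <- simulate_sample(sim_sample_spec(fetal_fraction = 0.3, seed = 12L), g)
  expect_true(all(s$profile$n_short_100_150 <= s$profile$n_total))
})

test_that("invalid specs are rejected and ff=0 with fetal events warns", {
  g <- test_genome()
  expect_error(sim_sample_spec(fetal_fraction = 1.2), "\\[0, 1\\]")
  expect_error(genomic_event("chr1", 5, 2, copy_number = 3), "start")
  expect_error(genomic_event("chr5", copy_number = 2), "copy_number")
  bad <- sim_sample_spec(fetal_events = list(genomic_event("chr1", 0, 1e9, copy_number = 3)),
                         placental_events = list(genomic_event("chr1", 0, 1e9, copy_number = 3)))
  expect_error(simulate_sample(bad, g), "beyond")
  w <- sim_sample_spec(fetal_fraction = 0,
                       fetal_events = list(genomic_event("chr21", copy_number = 3)))
  expect_warning(simulate_sample(w, g), "undetectable")
})
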