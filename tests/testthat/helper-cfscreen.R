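# Shared fixtures, built once per test run. Everything is generated in code
# from fixed seeds; nothing is read from disk except the packaged count
# fixtures under inst/extdata.

test_env <- new.env(parent = emptyenv())

test_genome <- function() {
  if (is.null(test_env$genome)) test_env$genome <- synthetic_genome(seed = 1L)
  test_env$genome
}

test_config <- function() run_config()

test_y_cal <- function() {
  if (is.null(test_env$y_cal)) {
    test_env$y_cal <- calibrate_y_reference(test_genome(), n = 20L, seed = 2L)
  }
  test_env$y_cal
}

test_seqff_model <- function() {
  if (is.null(test_env$seqff)) {
    cal <- simulate_seqff_calibration(n = 30L, genome = test_genome(),
                                      seed = 4L)
    test_env$seqff <- train_seqff(cal)
  }
  test_env$seqff
}

# 25-sample euploid female panel (tests that need a full 50-sample panel
# build their own)
test_panel <- function() {
  if (is.null(test_env$panel)) {
    g <- test_genome()
    samples <- lapply(1:25, function(i) {
      normalize_bintable(simulate_sample(
        sim_sample_spec(sample_id = paste0("P", i), fetal_sex = "female",
                        fetal_fraction = 0.15, seed = 100L + i), g)$bins)
    })
    test_env$panel <- build_panel(samples)
  }
  test_env$panel
}

screen_scenario <- function(scenario, seed, ff = 0.2, ...) {
  g <- test_genome()
  s <- simulate_sample(
    scenario_sample_spec(scenario, scenario, g, ff = ff, seed = seed, ...), g)
  list(sample = s,
       calls = screen_sample(s, test_panel(), test_seqff_model(),
                             test_y_cal(), test_config()),
       diagnostic = truth_to_diagnostic(s$truth, g))
}

# piecewise-constant signal with well-separated steps, for changepoint tests
step_signal <- function(n, bounds, means, sd, seed) {
  with_seed(seed, {
    starts <- c(1L, bounds + 1L)
    ends <- c(bounds, n)
    x <- numeric(n)
    for (i in seq_along(starts)) x[starts[i]:ends[i]] <- means[i]
    x + stats::rnorm(n, 0, sd)
  })
}
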