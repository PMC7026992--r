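# Virtual-population sampling and Monte Carlo regimen simulation.

test_that("degenerate sampler returns the reference means", {
  draws <- sample_population(population_sampler("degenerate"), 3, seed = 1)
  ref <- reference_parameters()
  for (i in 1:3) expect_equal(unname(draws[i, ]), ref$mean)
})

test_that("parametric sampler reproduces the target moments", {
  draws <- sample_population(population_sampler(), 1e5, seed = 123)
  ref <- reference_parameters()
  rel_mean <- abs(colMeans(draws) - ref$mean) / ref$mean
  expect_true(all(rel_mean < 0.01))
  # SD within 2.5%: the prescribed +/- 4 SD truncation shaves the upper
  # tail of the most skewed parameters (K21 has CV 0.83)
  rel_sd <- abs(apply(draws, 2, sd) - ref$sd) / ref$sd
  expect_true(all(rel_sd < 0.025))
  expect_true(all(draws > 0))
})

test_that("sampling is deterministic given the seed", {
  s <- population_sampler()
  expect_identical(sample_population(s, 50, seed = 9),
                   sample_population(s, 50, seed = 9))
  expect_false(identical(sample_population(s, 50, seed = 9),
                         sample_population(s, 50, seed = 10)))
})

test_that("nonparametric sampler resamples support points by weight", {
  m <- toy_pop_model(n_points = 3, seed = 4)
  m$weights <- c(1, 0, 0)
  draws <- sample_population(population_sampler("nonparametric", model = m),
                             20, seed = 2)
  for (i in 1:20) {
    expect_equal(unname(draws[i, ]), unname(unlist(m$support[1, ])))
  }
})

test_that("degenerate-sampler continuous infusion reproduces the
           closed-form day-3 AUC", {
  res <- simulate_regimen(plain_ci(2000), population_sampler("degenerate"),
                          n = 1, seed = 1, grid = seq(0, 72, by = 0.1))
  # Css = 250 / mean CL; 24 h window AUC = 24 * Css
  expect_equal(res$subjects$auc_plasma, 24 * 250 / 12.464,
               tolerance = 1e-3)
  expect_equal(res$subjects$penetration_pct,
               steady_state_penetration(
                 as_structural_params(setNames(reference_parameters()$mean,
                                               param_names()))),
               tolerance = 5e-3)
})

test_that("doubling the dose doubles exposure (linearity, common seed)", {
  sm <- population_sampler()
  r1 <- simulate_regimen(plain_ci(1000), sm, n = 30, seed = 5)
  r2 <- simulate_regimen(plain_ci(2000), sm, n = 30, seed = 5)
  expect_equal(r2$subjects$auc_plasma, 2 * r1$subjects$auc_plasma,
               tolerance = 1e-8)
  expect_equal(r2$subjects$auc_elf, 2 * r1$subjects$auc_elf,
               tolerance = 1e-8)
})

test_that("regimen summaries are reproducible and their percentile bands
           nested", {
  sm <- population_sampler()
  a <- simulate_regimen("2g_ld_1g_q8h_ci", sm, n = 50, seed = 77)
  b <- simulate_regimen("2g_ld_1g_q8h_ci", sm, n = 50, seed = 77)
  expect_identical(a$subjects, b$subjects)
  expect_true(all(a$percentiles[, "p5"] <= a$percentiles[, "p50"]))
  expect_true(all(a$percentiles[, "p50"] <= a$percentiles[, "p95"]))
  # median simulated penetration equals the per-subject closed form
  closed <- apply(a$params, 1, function(p)
    100 * (p["V"] * p["K13"]) / (p["K31"] * p["V_ELF"]))
  expect_equal(median(a$subjects$penetration_pct), median(closed),
               tolerance = 5e-3)
})

test_that("trough_series picks interval-end concentrations", {
  p <- med_params()
  prof <- solve_profile(p, plain_ci(1000), seq(0, 72, by = 0.1))
  tr <- trough_series(prof)
  expect_length(tr, 9)
  # at steady state the CI trough equals Css
  expect_equal(unname(tr[9]), unname(steady_state(p, 125)["css_plasma"]),
               tolerance = 1e-3)
  expect_error(trough_series(solve_profile(p, plain_ci(1000, 24),
                                           seq(0, 24))), "horizon")
})

test_that("toxicity_probability hits its trivial bounds and is
           dose-monotone", {
  sm <- population_sampler()
  expect_equal(toxicity_probability(plain_ci(1000), sm, n = 100,
                                    threshold = 1e-9, seed = 3), 1)
  expect_equal(toxicity_probability(plain_ci(1000), sm, n = 100,
                                    threshold = Inf, seed = 3), 0)
  t2 <- toxicity_probability(plain_ci(2000), sm, n = 200, seed = 3)
  t8 <- toxicity_probability(plain_ci(8000), sm, n = 200, seed = 3)
  expect_lte(t2, t8)
})
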