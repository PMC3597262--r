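test_that("perturbation adds a fixed share of the mean and inverts
           exactly", {
  x <- c(8, 10, 12)
  expect_equal(perturb_series(x, 25), x + 2.5)
  expect_identical(perturb_series(x, 0), x)
  ## +15 then -15 (against the unperturbed reference) restores the series
  up <- perturb_series(x, 15)
  expect_equal(perturb_series(up, -15, reference_mean = mean(x)), x,
               tolerance = 1e-12)
  expect_error(perturb_series(numeric(0), 10), "empty")
})

test_that("phase trajectories fit the resource-on-consumer line", {
  cons <- c(1, 2, 3, 4, 5)
  tr <- phase_trajectory(cons, 2 * cons, years = 1971:1975,
                         window = 1971:1975)
  expect_equal(tr$slope, 2)
  expect_equal(tr$intercept, 0, tolerance = 1e-12)
  ## closed-form least squares oracle
  set.seed(61)
  x <- rnorm(12); y <- rnorm(12)
  tr2 <- phase_trajectory(x, y, years = 1:12, window = 1:12)
  expect_equal(tr2$slope, cov(x, y) / var(x), tolerance = 1e-10)
  expect_equal(tr2$slope, unname(coef(lm(y ~ x))[2]), tolerance = 1e-10)
  ## degenerate consumer flagged
  tr3 <- phase_trajectory(rep(1, 5), rnorm(5), years = 1:5, window = 1:5)
  expect_true(tr3$degenerate)
  expect_true(is.na(tr3$slope))
  expect_error(phase_trajectory(1:2, 1:2, years = 1:2, window = 1:2),
               ">= 3 years")
  ## endpoint chord option
  tr4 <- phase_trajectory(c(0, 3, 1, 2), c(0, 9, 1, 4), years = 1:4,
                          window = 1:4, method = "chord")
  expect_equal(tr4$slope, (4 - 0) / (2 - 0))
})

test_that("scenario comparison reports slope changes antisymmetrically and
           flags sign flips", {
  a <- phase_trajectory(1:5, (1:5) * 1, years = 1:5, window = 1:5)
  b <- phase_trajectory(1:5, (1:5) * -1, years = 1:5, window = 1:5)
  cmp <- compare_scenarios(a, b)
  expect_true(cmp$sign_flip)
  expect_true(cmp$shift)
  expect_equal(cmp$difference, -2)
  cmp_rev <- compare_scenarios(b, a)
  expect_equal(cmp_rev$difference, -cmp$difference)
  same <- compare_scenarios(a, a)
  expect_equal(same$difference, 0)
  expect_false(same$shift)
  c5 <- phase_trajectory(1:5, 1:5, years = 2:6, window = 2:6)
  expect_error(compare_scenarios(a, c5), "window")
})

test_that("a zero-delta scenario is bit-identical to its baseline and a
           perturbation touches only its target", {
  case <- gen_threshold_crossing_case(seed = 62)
  fw <- fit_foodweb(case$data, case$structures)
  run0 <- run_scenario(fw, scenario_spec("P", 0, case$window),
                       n_runs = 30, seed = 63)
  expect_identical(run0$baseline$trajectories, run0$scenario$trajectories)
  mod <- as.data.frame(case$data)
  mod$P <- perturb_series(mod$P, 25)
  for (v in setdiff(names(mod), "P"))
    expect_identical(mod[[v]], as.data.frame(case$data)[[v]])
})

test_that("raising phosphorus above the threshold activates the
           high-regime response and flips the herbivore-autotroph slope", {
  case <- gen_threshold_crossing_case(seed = 64)
  fw <- fit_foodweb(case$data, case$structures)
  run <- run_scenario(fw, scenario_spec("P", 40, case$window),
                      n_runs = 100, seed = 65)
  ## regime occupancy in the analysis window changes
  theta <- fw$fits$PHY$threshold$value
  base_above <- sum(as.data.frame(case$data)$P[case$window] > theta)
  scen_above <- sum(perturb_series(as.data.frame(case$data)$P,
                                   40)[case$window] > theta)
  expect_lte(base_above, 2)
  expect_gt(scen_above, length(case$window) * 0.8)
  tb <- sim_phase_trajectory(run$baseline, "ZOO", "PHY", case$window)
  ts <- sim_phase_trajectory(run$scenario, "ZOO", "PHY", case$window)
  expect_true(compare_scenarios(tb, ts)$sign_flip)
  ## the fish-zooplankton link is untouched by a phosphorus scenario
  tb2 <- sim_phase_trajectory(run$baseline, "FIS", "ZOO", case$window)
  ts2 <- sim_phase_trajectory(run$scenario, "FIS", "ZOO", case$window)
  expect_false(compare_scenarios(tb2, ts2)$sign_flip)
})

test_that("the full scenario grid runs end-to-end over both targets", {
  case <- gen_threshold_crossing_case(seed = 66, n_years = 40)
  fw <- fit_foodweb(case$data, case$structures)
  tab <- scenario_grid(fw, targets = c("P", "FIS"),
                       deltas = c(-25, -15, 15, 25),
                       window = 10:25, n_runs = 40, seed = 67)
  expect_equal(nrow(tab), 2 * 4 * 2)
  expect_true(all(is.finite(tab$slope_baseline)))
  expect_true(all(is.finite(tab$slope_scenario)))
  ## FIS scenarios run in biotic-shift (fish-observed) mode
  expect_true(all(tab$pair %in% c("ZOO/PHY", "FIS/ZOO")))
})
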