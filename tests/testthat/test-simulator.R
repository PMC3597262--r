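fit_small_web <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- gen_default_foodweb(50, seed = 51)
      cache <<- list(data = d, fit = fit_foodweb(d))
    }
    cache
  }
})

test_that("one-step prediction equals direct evaluation of the active
           regime's partial effects", {
  fw <- fit_small_web()$fit
  d <- fit_small_web()$data
  state <- c(PHY = 0.2, ZOO = 0.5, GEL = -1.2, FIS = -1.5)
  drivers <- c(PRE = 0.3, F = 0.1, SST = -0.4, NAO = 0.2, P = 40)
  out <- one_step_predict(fw, state, drivers)
  nd <- as.data.frame(as.list(c(state, drivers)))
  for (r in names(fw$fits)) {
    f <- fw$fits[[r]]
    reg <- if (f$threshold$kind == "none") "low"
           else assign_regime(f$threshold, nd)
    manual <- f$intercept + f$high_offset * (reg == "high")
    tt <- f$terms
    for (j in seq_len(nrow(tt))) {
      active <- tt$code[j] == 0L ||
        (tt$code[j] == 1L && reg == "low") ||
        (tt$code[j] == 2L && reg == "high")
      if (!active) next
      cols <- which(f$block == j)
      B <- ncs_eval(f$bases[[tt$term[j]]], nd[[tt$var[j]]])
      manual <- manual +
        drop((B %*% f$bases[[tt$term[j]]]$Z) %*% f$beta[cols])
    }
    expect_equal(unname(out[r]), unname(manual), tolerance = 1e-10)
  }
  ## purity: repeated calls identical
  expect_identical(out, one_step_predict(fw, state, drivers))
})

test_that("a model with zeroed coefficients predicts its intercept", {
  fw <- fit_small_web()$fit
  z <- fw
  for (r in names(z$fits)) {
    z$fits[[r]]$beta[-1] <- 0
    z$fits[[r]]$high_offset <- 0
  }
  out <- one_step_predict(z, c(PHY = 1, ZOO = -1, GEL = 0.5, FIS = 2),
                          c(PRE = 0, F = 0, SST = 0, NAO = 0, P = 50))
  ints <- vapply(z$fits, function(f) unname(f$intercept), 0)
  expect_equal(unname(out), unname(ints), tolerance = 1e-12)
})

test_that("error-vector resampling is uniform over years and preserves the
           contemporaneous correlation", {
  E <- matrix(rnorm(8), 2, 4)
  set.seed(52)
  one <- resample_error_vector(E[1, , drop = FALSE], 5)
  expect_true(all(one == rep(E[1, ], each = 5)))
  draws <- resample_error_vector(E, 1e4)
  hit1 <- mean(draws[, 1] == E[1, 1])
  expect_lt(abs(hit1 - 0.5), 0.02)
  ## correlation preservation on a realistic residual matrix
  fw <- fit_small_web()$fit
  set.seed(53)
  dr <- resample_error_vector(fw$residual_matrix, 1e4)
  expect_lt(max(abs(cor(dr) - cor(fw$residual_matrix))), 0.05)
  expect_error(resample_error_vector(fw$residual_matrix[0, ]), "empty")
})

test_that("with noise off all runs coincide with the deterministic
           recursion", {
  fw <- fit_small_web()$fit
  d <- fit_small_web()$data
  sim <- simulate_foodweb(fw, n_runs = 7, seed = 54, noise = FALSE,
                          start_year = 2, horizon = 10)
  spread <- apply(sim$trajectories, c(2, 3), function(z) diff(range(z)))
  expect_lt(max(spread), 1e-12)
  expect_equal(sim$band_low, sim$mean, tolerance = 1e-12)
  expect_equal(sim$band_high, sim$mean, tolerance = 1e-12)
  ## manual recursion with one_step_predict
  state <- unlist(d[d$year == 2, c("PHY", "ZOO", "GEL", "FIS")])
  for (k in 1:10) {
    drv <- unlist(d[d$year == 1 + k, c("PRE", "F", "SST", "NAO", "P")])
    state <- one_step_predict(fw, state, drv)
    expect_equal(unname(sim$mean[k + 1, ]), unname(state),
                 tolerance = 1e-10)
  }
})

test_that("a one-year horizon is exactly the one-step prediction from the
           observations", {
  fw <- fit_small_web()$fit
  d <- fit_small_web()$data
  sim <- simulate_foodweb(fw, n_runs = 3, seed = 55, noise = FALSE,
                          start_year = 10, horizon = 1)
  manual <- one_step_predict(
    fw, unlist(d[d$year == 10, c("PHY", "ZOO", "GEL", "FIS")]),
    unlist(d[d$year == 10, c("PRE", "F", "SST", "NAO", "P")]))
  expect_equal(unname(sim$mean[2, ]), unname(manual), tolerance = 1e-12)
})

test_that("simulations are seed-reproducible and band limits bracket the
           ensemble mean", {
  fw <- fit_small_web()$fit
  s1 <- simulate_foodweb(fw, n_runs = 50, seed = 56, horizon = 20,
                         start_year = 2)
  s2 <- simulate_foodweb(fw, n_runs = 50, seed = 56, horizon = 20,
                         start_year = 2)
  expect_identical(s1$trajectories, s2$trajectories)
  s3 <- simulate_foodweb(fw, n_runs = 50, seed = 57, horizon = 20,
                         start_year = 2)
  expect_false(identical(s1$trajectories, s3$trajectories))
  expect_true(all(s1$band_low <= s1$mean + 1e-12))
  expect_true(all(s1$band_high >= s1$mean - 1e-12))
})

test_that("percentile bands widen when residual variance is scaled up", {
  fw <- fit_small_web()$fit
  big <- fw
  big$residual_matrix <- fw$residual_matrix * 3
  s1 <- simulate_foodweb(fw, n_runs = 300, seed = 58, horizon = 15,
                         start_year = 2)
  s2 <- simulate_foodweb(big, n_runs = 300, seed = 58, horizon = 15,
                         start_year = 2)
  w1 <- mean(s1$band_high - s1$band_low)
  w2 <- mean(s2$band_high - s2$band_low)
  expect_gt(w2, w1)
})

test_that("horizons beyond driver coverage and missing drivers are
           rejected", {
  fw <- fit_small_web()$fit
  expect_error(simulate_foodweb(fw, n_runs = 2, start_year = 2,
                                horizon = 100), "coverage")
  expect_error(one_step_predict(fw, c(PHY = 0, ZOO = 0, GEL = 0, FIS = 0),
                                c(F = 0, SST = 0, NAO = 0, P = 50)),
               "PRE")
})

test_that("fish-observed mode pins the simulated FIS to the observations", {
  fw <- fit_small_web()$fit
  d <- fit_small_web()$data
  sim <- simulate_foodweb(fw, n_runs = 20, seed = 59, horizon = 12,
                          start_year = 2, fish_observed = TRUE)
  obs <- d$FIS[match(sim$years, d$year)]
  expect_equal(unname(sim$mean[-1, "FIS"]), obs[-1], tolerance = 1e-12)
})
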