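test_that("regime assignment follows the <= theta convention", {
  ts <- threshold_spec("P", value = 47.52)
  expect_equal(assign_regime(ts, data.frame(P = 50)), "high")
  expect_equal(assign_regime(ts, data.frame(P = 47.52)), "low")
  expect_equal(assign_regime(ts, data.frame(P = c(10, 47.53))),
               c("low", "high"))
  expect_error(assign_regime(ts, data.frame(Q = 1)), "P")
  expect_error(assign_regime(ts, data.frame(P = NA_real_)), "missing")
})

test_that("line thresholds put high zooplankton / low jellyfish below the
           line in the high regime, with on-line points low", {
  ts <- threshold_spec(c("ZOO", "GEL"), value = c(1.07, 2.18))
  expect_equal(assign_regime(ts, data.frame(ZOO = 1, GEL = 0)), "high")
  ## a point exactly on the line goes low
  expect_equal(assign_regime(ts, data.frame(ZOO = 1, GEL = 1.07 + 2.18)),
               "low")
  expect_equal(assign_regime(ts, data.frame(ZOO = -1, GEL = 2)), "low")
})

test_that("candidate thresholds are order-statistic midpoints truncated by
           the minimum regime fraction", {
  expect_equal(candidate_thresholds(1:10, 0.2), seq(2.5, 8.5, by = 1))
  expect_equal(candidate_thresholds(1:10, 0.5), 5.5)
  expect_error(candidate_thresholds(1:11, 0.5), "smaller")
  grid <- candidate_thresholds(c(1, 2, 2, 2, 3, 4, 4, 5, 6, 7), 0.1)
  expect_true(all(diff(grid) > 0))
})

test_that("a clean level switch is recovered exactly in the correct gap", {
  x <- seq(1, 40)
  d <- data.frame(x = x, y = ifelse(x <= 17.2, 1, 3))
  st <- model_structure("y", threshold_spec("x"))
  fit <- tgam(st, d)
  expect_gt(fit$threshold$value, 17)
  expect_lt(fit$threshold$value, 18)
  expect_lt(max(abs(fit$residuals)), 1e-8)
  expect_equal(unname(fit$intercept + fit$high_offset), 3, tolerance = 1e-8)
})

test_that("the selected threshold minimises the recorded GCV profile and
           every candidate partitions all observations", {
  d <- gen_strong_threshold(60, seed = 21)
  fit <- tgam(st_threshold(), d)
  pr <- fit$profile
  sel <- pr$gcv[which.min(abs(pr$theta - fit$threshold$value))]
  expect_true(all(sel <= pr$gcv[is.finite(pr$gcv)] + 1e-12))
  expect_true(all(pr$n_low + colSums(outer(d$x, pr$theta, ">")) == nrow(d)))
  ## exhaustive re-evaluation: refit at a handful of other candidates
  for (th in pr$theta[is.finite(pr$gcv)][c(3, 11, 25)]) {
    alt <- tgam(st_threshold(), d, fixed_threshold = th)
    expect_gte(alt$gcv + 1e-10, fit$gcv)
  }
})

test_that("refitting the same data twice is bit-identical", {
  d <- gen_strong_threshold(50, seed = 22)
  f1 <- tgam(st_threshold(), d)
  f2 <- tgam(st_threshold(), d)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$threshold$value, f2$threshold$value)
})

test_that("noise-free linearly separable regimes are reproduced exactly by
           the line search", {
  set.seed(23)
  n <- 80
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), z = runif(n, -1, 1))
  lab <- ifelse(d$x2 - d$x1 >= 0.2, "low", "high")
  d$y <- ifelse(lab == "low", -1, 1) * (1 + 0.3 * d$z)
  st <- model_structure("y", threshold_spec(c("x1", "x2")),
                        low = "z", high = "z")
  fit <- tgam(st, d, max_intercepts = 200)  # un-thinned intercept grid
  expect_equal(fit$regime, lab)
})

test_that("a vertical true line is recovered as a threshold on the first
           coordinate", {
  set.seed(24)
  n <- 200
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), z = rnorm(n))
  lab <- ifelse(d$x1 <= 0, "low", "high")   # line x1 = 0
  d$y <- ifelse(lab == "low", -0.5 - 0.5 * d$z, 0.5 + 0.5 * d$z) +
    rnorm(n, sd = 0.25)
  st <- model_structure("y", threshold_spec(c("x1", "x2")),
                        low = "z", high = "z")
  fit <- tgam(st, d)
  expect_gte(mean(fit$regime == lab), 0.95)
})

test_that("genuine leave-one-out CV matches the hat-matrix shortcut for a
           plain linear model and vanishes on noiseless data", {
  set.seed(25)
  n <- 30
  d <- data.frame(z = rnorm(n))
  d$y <- 1 + 2 * d$z + rnorm(n)
  st <- model_structure("y", whole = "z", n_knots = 2)
  cv <- genuine_cv(st, d)
  lmf <- lm(y ~ z, data = d)
  shortcut <- mean((resid(lmf) / (1 - lm.influence(lmf)$hat))^2)
  expect_equal(as.numeric(cv), shortcut, tolerance = 1e-8)
  d$y <- 1 + 2 * d$z
  expect_lt(as.numeric(genuine_cv(st, d)), 1e-16)
})

test_that("per-fold threshold re-search genuinely changes the CV score on
           threshold-bearing data", {
  d <- gen_strong_threshold(40, seed = 26)
  cv_full <- genuine_cv(st_threshold(), d, refit_threshold = TRUE)
  cv_fix <- genuine_cv(st_threshold(), d, refit_threshold = FALSE)
  expect_false(isTRUE(all.equal(as.numeric(cv_full), as.numeric(cv_fix))))
})

test_that("comparing a specification against itself is reported as a tie", {
  d <- gen_additive_truth(30, seed = 27)
  cmp <- compare_models(st_additive(), st_additive(), d)
  expect_true(cmp$tie)
  expect_equal(cmp$selected, "tie")
})

test_that("failed folds are tolerated up to 10 percent and reported", {
  d <- gen_strong_threshold(40, seed = 28)
  cv <- genuine_cv(st_threshold(), d)
  expect_equal(attr(cv, "n_failed"), 0)
  expect_equal(sum(!is.na(attr(cv, "fold_errors"))), 40)
})
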