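test_that("unpenalized fit reproduces ordinary least squares", {
  set.seed(2)
  n <- 50
  x <- runif(n)
  y <- sin(3 * x) + rnorm(n, sd = 0.2)
  b <- ncs_basis(x, 4, "x")
  f0 <- fit_additive(y, list(b), lambda = 0)
  ols <- lm(y ~ ncs_eval(b, x) - 1)
  expect_lt(max(abs(f0$fitted - fitted(ols))), 1e-8)
})

test_that("an infinite penalty drives a term to a straight line with edf 1", {
  set.seed(3)
  x <- runif(60)
  y <- sin(3 * x) + rnorm(60, sd = 0.2)
  fit <- fit_additive(y, list(ncs_basis(x, 4, "x")), lambda = 1e12)
  expect_equal(unname(fit$edf["x"]), 1, tolerance = 0.01)
  curve <- predict(fit, data.frame(x = seq(0, 1, length.out = 20)),
                   type = "terms")[, 1]
  expect_lt(max(abs(diff(diff(curve)))), 1e-6)
})

test_that("a constant response yields its mean and zero partial effects", {
  x <- runif(30)
  fit <- fit_additive(rep(4.2, 30), list(ncs_basis(x, 4, "x")))
  expect_equal(fit$intercept, 4.2, tolerance = 1e-8)
  expect_lt(max(abs(predict(fit, type = "terms"))), 1e-8)
  expect_lte(fit$r2_adj, 0)
})

test_that("GCV matches its closed form and scales with residual variance", {
  set.seed(4)
  n <- 20
  x <- runif(n)
  y <- 2 * x + rnorm(n)
  fit <- fit_additive(y, list(ncs_basis(x, 2, "x")))
  rss <- sum(resid(lm(y ~ x))^2)
  expect_equal(gcv_score(fit), n * rss / (n - 2)^2, tolerance = 1e-10)
  ## doubling the response at fixed H doubles residuals: GCV x4
  f1 <- fit_additive(y, list(ncs_basis(x, 4, "x")), lambda = 5)
  f2 <- fit_additive(2 * y, list(ncs_basis(x, 4, "x")), lambda = 5)
  expect_equal(f2$gcv, 4 * f1$gcv, tolerance = 1e-8)
  ## a perfect fit has GCV 0
  fp <- fit_additive(3 * x + 1, list(ncs_basis(x, 2, "x")))
  expect_lt(gcv_score(fp), 1e-16)
})

test_that("the fit is a linear smoother at fixed smoothing parameters", {
  set.seed(5)
  x <- runif(40)
  y1 <- rnorm(40)
  y2 <- rnorm(40)
  fs <- function(y) fit_additive(y, list(ncs_basis(x, 4, "x")),
                                 lambda = 0.7)$fitted
  expect_lt(max(abs(fs(y1 + y2) - fs(y1) - fs(y2))), 1e-8)
})

test_that("edf is non-increasing in the smoothing parameter", {
  set.seed(6)
  x <- runif(50)
  y <- sin(4 * x) + rnorm(50, sd = 0.3)
  lams <- 10^seq(-4, 6, by = 1)
  edfs <- vapply(lams, function(l)
    unname(fit_additive(y, list(ncs_basis(x, 4, "x")),
                        lambda = l)$edf["x"]), 0)
  expect_true(all(diff(edfs) <= 1e-8))
})

test_that("prediction is exact in-sample, constant for intercept-only
           models, and errors on missing covariates", {
  set.seed(7)
  x <- runif(30)
  y <- cos(2 * x) + rnorm(30, sd = 0.1)
  fit <- fit_additive(y, list(ncs_basis(x, 3, "x")))
  expect_lt(max(abs(predict(fit, data.frame(x = x)) - fit$fitted)), 1e-10)
  f0 <- fit_additive(y, list())
  expect_equal(unique(predict(f0, data.frame(q = 1:5))), mean(y))
  expect_error(predict(fit, data.frame(z = 1:3)), "x")
})

test_that("term p-values reduce to the classical F-test for linear terms
           and are 1 for a zeroed term", {
  set.seed(8)
  n <- 40
  x <- runif(n)
  w <- runif(n)
  y <- 2 * x + rnorm(n)
  fit <- fit_additive(y, list(ncs_basis(x, 2, "x"), ncs_basis(w, 2, "w")))
  ref <- summary(lm(y ~ x + w))$coefficients
  expect_equal(term_p_value(fit, "x"), ref["x", 4], tolerance = 1e-6)
  expect_equal(term_p_value(fit, "w"), ref["w", 4], tolerance = 1e-6)
  zfit <- fit
  zfit$beta[zfit$block == 1] <- 0
  expect_gte(term_p_value(zfit, "x"), 0.99)
})

test_that("invalid inputs are rejected with informative errors", {
  x <- runif(20)
  expect_error(fit_additive(c(rnorm(19), NA), list(ncs_basis(x, 4, "x"))),
               "finite")
  expect_error(fit_additive(rnorm(20),
                            list(ncs_basis(x, 4, "a"),
                                 ncs_basis(x, 4, "b")), lambda = 0),
               "collinear")
  expect_error(gcv_score(list(n = 5, trh = 6, rss = 1)), "saturated")
})

test_that("the estimated curve agrees with an independent GAM fit", {
  skip_if_not_installed("mgcv")
  set.seed(9)
  n <- 200
  x <- runif(n, -2, 2)
  y <- sin(x) + rnorm(n, sd = 0.3)
  fit <- fit_additive(y, list(ncs_basis(x, 4, "x")))
  ref <- mgcv::gam(y ~ s(x, k = 4, bs = "cr"))
  expect_lt(sqrt(mean((fit$fitted - fitted(ref))^2)), 0.1)
})

test_that("curve estimation error shrinks as n grows", {
  truth <- function(x) sin(2 * x)
  mse <- function(n, seed) {
    set.seed(seed)
    x <- runif(n, -2, 2)
    y <- truth(x) + rnorm(n, sd = 0.3)
    fit <- fit_additive(y, list(ncs_basis(x, 4, "x")))
    mean((fit$fitted - truth(x))^2)
  }
  m50 <- mean(vapply(1:20, function(s) mse(50, s), 0))
  m500 <- mean(vapply(1:20, function(s) mse(500, s + 100), 0))
  expect_lt(m500, m50)
})
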