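test_that("standardization is exact, invertible and idempotent", {
  z <- standardize(c(2, 4, 6))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  x <- rnorm(20, mean = 5, sd = 3)
  s <- standardize(x)
  expect_equal(unstandardize(s, attr(s, "record")), x, tolerance = 1e-12)
  expect_equal(as.numeric(standardize(as.numeric(s))), as.numeric(s),
               tolerance = 1e-12)
  expect_error(standardize(rep(1, 5)), "zero sd")
  expect_error(standardize(c(1, NA, NA)), "non-missing")
})

test_that("lagging shifts by whole years and composes", {
  x <- c(10, 11, 12, 13, 14, 15)   # years 1960-1965
  l1 <- lag_series(x, 1)
  expect_equal(l1[2], 10)           # 1961 holds the 1960 value
  expect_true(is.na(l1[1]))
  expect_error(lag_series(x, 0), "k must be")
  expect_equal(lag_series(lag_series(x, 1), 1), lag_series(x, 2))
  expect_warning(all_na <- lag_series(x, 6), "length")
  expect_true(all(is.na(all_na)))
})

test_that("the four published model structures are encoded faithfully", {
  ps <- published_structures()
  expect_named(ps, c("PHY", "ZOO", "GEL", "FIS"))
  expect_equal(ps$PHY$threshold$var, "P")
  expect_equal(ps$PHY$low, "ZOO")
  expect_equal(ps$PHY$high, "NAO")
  expect_equal(ps$PHY$whole, "GEL")
  expect_equal(ps$ZOO$threshold$var, "FIS")
  expect_equal(ps$ZOO$high, "PRE")
  expect_setequal(ps$ZOO$low, c("GEL", "SST", "PHY"))
  expect_equal(ps$GEL$low, "ZOO")
  expect_setequal(ps$GEL$high, c("ZOO", "PHY"))
  expect_equal(ps$FIS$threshold$kind, "bivariate_line")
  expect_equal(ps$FIS$threshold$var, c("ZOO", "GEL"))
  expect_equal(ps$FIS$low, "F")
  expect_true(all(vapply(ps, function(s) s$n_knots, 0) <= 4))
})

test_that("dataset construction validates years and flags unknown columns", {
  df <- data.frame(year = c(3, 1, 2), PHY = c(3, 1, 2), junk = 1:3)
  expect_warning(d <- foodweb_data(df, standardize = FALSE), NA)
  expect_equal(d$year, 1:3)
  expect_equal(d$PHY, c(1, 2, 3))
  expect_equal(attr(d, "unknown_columns"), "junk")
  expect_error(foodweb_data(data.frame(PHY = 1:3)), "year")
  expect_error(foodweb_data(data.frame(year = c(1, 1, 2), PHY = 1:3)),
               "duplicate")
})

test_that("CSV round-trips preserve the dataset and reject corrupt input", {
  d <- gen_default_foodweb(20, seed = 41)
  path <- tempfile(fileext = ".csv")
  write_foodweb_csv(d, path)
  d2 <- read_foodweb_csv(path)
  expect_equal(as.data.frame(d), as.data.frame(d2), tolerance = 1e-12,
               ignore_attr = TRUE)
  ## shuffled rows come back year-sorted
  shuf <- as.data.frame(d)[sample(nrow(d)), ]
  write.csv(shuf, path, row.names = FALSE)
  d3 <- read_foodweb_csv(path)
  expect_equal(d3$year, d$year)
  expect_equal(d3$PHY, d$PHY, tolerance = 1e-12)
  writeLines(c("year,PHY", "1,2.0", "2,oops"), path)
  expect_error(read_foodweb_csv(path), "PHY")
})

test_that("ground truth serialises to a YAML sidecar", {
  path <- tempfile(fileext = ".yaml")
  write_truth_yaml(true_params_default(), path)
  obj <- yaml::read_yaml(path)
  expect_named(obj$models, c("PHY", "ZOO", "GEL", "FIS"))
  expect_equal(obj$models$PHY$threshold$value[[1]], 52)
})

test_that("food-web fitting is deterministic and reports coherent adjusted
           R-squared and residual diagnostics", {
  d <- gen_default_foodweb(60, seed = 42)
  fw1 <- fit_foodweb(d)
  fw2 <- fit_foodweb(d)
  expect_identical(fw1$summary, fw2$summary)
  for (r in names(fw1$fits)) {
    f <- fw1$fits[[r]]
    e <- residuals(f)
    tss <- sum((f$mf[[r]] - mean(f$mf[[r]]))^2)
    r2 <- 1 - (f$rss / (f$n - f$trh)) / (tss / (f$n - 1))
    expect_equal(f$r2_adj, r2, tolerance = 1e-10)
    expect_equal(sum(e), 0, tolerance = 1e-6)
  }
  expect_setequal(fw1$diagnostics$response, c("PHY", "ZOO", "GEL", "FIS"))
  expect_true(all(is.finite(fw1$diagnostics$acf1)))
  expect_true(all(fw1$diagnostics$shapiro_p >= 0))
})

test_that("a constant response aborts with the response named", {
  d <- gen_default_foodweb(30, seed = 43)
  d$GEL <- 0
  expect_error(fit_foodweb(d), "GEL")
})

test_that("residuals of well-specified fits look like white noise", {
  n_rep <- 40
  ok <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    d <- gen_default_foodweb(150, seed = 500 + i)
    f <- fit_foodweb(d, structures = published_structures()["GEL"])$fits$GEL
    a1 <- acf(residuals(f), lag.max = 1, plot = FALSE)$acf[2]
    ok[i] <- abs(a1) < 2 / sqrt(f$n)
  }
  expect_gte(mean(ok), 0.9)
})

test_that("jointly fitting all four models recovers every threshold to
           within one order statistic in most replicates", {
  n_rep <- 25
  joint <- logical(n_rep)
  tr <- true_params_default()
  for (i in seq_len(n_rep)) {
    d <- gen_default_foodweb(201, seed = 600 + i)
    fw <- tryCatch(fit_foodweb(d), error = function(e) NULL)
    if (is.null(fw)) next
    ok <- TRUE
    for (r in c("PHY", "ZOO", "GEL")) {
      thr <- fw$fits[[r]]$threshold
      tv <- tr$models[[r]]$threshold$value
      lx <- sort(lag_series(d[[thr$var]], 1)[-1])
      gap <- findInterval(thr$value, lx) - findInterval(tv, lx)
      ok <- ok && abs(gap) <= 1
    }
    ## fish line: partition agreement with the true line
    u <- lag_series(d$GEL, 1) - lag_series(d$ZOO, 1)
    truelab <- ifelse(u[-1] >= 0, "low", "high")
    ok <- ok && mean(fw$fits$FIS$regime == truelab) >= 0.9
    joint[i] <- ok
  }
  expect_gte(mean(joint), 0.7)
})
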