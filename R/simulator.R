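## Coupled forward simulation of the fitted food web.  Observations at the
## start year seed the biotic state; thereafter biotic covariates come from
## the model's own predictions while the external drivers (SST, NAO, P, F,
## PRE) stay at their observed values.  Noise is added by resampling whole
## year-rows of the four-model residual matrix, which preserves the
## contemporaneous correlation of errors across trophic levels.

BIOTIC <- c("PHY", "ZOO", "GEL", "FIS")
DRIVERS <- c("PRE", "F", "SST", "NAO", "P")

## advance every run one year: state (n_runs x 4) holds the biotic values at
## year t, driver_row the observed drivers at year t; returns predictions
## for year t+1
fw_step <- function(fits, state, driver_row) {
  n <- nrow(state)
  nd <- as.data.frame(state)
  for (v in names(driver_row)) nd[[v]] <- rep(driver_row[[v]], n)
  out <- matrix(NA_real_, n, length(fits),
                dimnames = list(NULL, names(fits)))
  for (r in names(fits)) out[, r] <- predict(fits[[r]], nd)
  out
}

#' One-step food-web prediction
#'
#' Evaluates the four fitted models at the supplied biotic state and driver
#' values (all playing the role of the lag-1 covariates) to predict the
#' biotic state one year ahead.  Regime assignment uses the supplied state.
#' The evaluation is deterministic (no noise).
#'
#' @param fit a [fit_foodweb()] result.
#' @param state named numeric vector (PHY, ZOO, GEL, FIS) at year t.
#' @param drivers named numeric vector (or one-row data frame) of the
#'   external drivers at year t.
#' @return named numeric vector of the predicted biotic state at t+1.
#' @export
one_step_predict <- function(fit, state, drivers) {
  stopifnot(inherits(fit, "foodweb_fit"))
  st <- matrix(as.numeric(state[BIOTIC]), 1, 4,
               dimnames = list(NULL, BIOTIC))
  if (any(is.na(st))) stop("state must supply PHY, ZOO, GEL and FIS")
  drv <- if (is.data.frame(drivers)) as.list(drivers[1, , drop = FALSE])
         else as.list(drivers)
  drop(fw_step(fit$fits, st, drv))
}

#' Resample a contemporaneous error vector
#'
#' Samples a year uniformly (with replacement) from the residual matrix and
#' returns that year's whole row of residuals, preserving the
#' contemporaneous correlation of errors across the four trophic levels.
#' Uses R's global random number stream.
#'
#' @param residual_matrix years x responses residual matrix.
#' @param n number of vectors to draw.
#' @return an `n` x responses matrix of resampled rows.
#' @export
resample_error_vector <- function(residual_matrix, n = 1) {
  residual_matrix <- as.matrix(residual_matrix)
  if (nrow(residual_matrix) == 0) stop("residual matrix is empty")
  idx <- sample.int(nrow(residual_matrix), n, replace = TRUE)
  residual_matrix[idx, , drop = FALSE]
}

#' Monte Carlo simulation of the coupled food web
#'
#' Initializes the biotic state from the observations at `start_year` and
#' propagates the four models forward for `horizon` annual steps.  External
#' drivers are fixed at their observed values; biotic covariates are fed
#' back from the simulation itself (optionally, `fish_observed = TRUE`
#' substitutes the observed planktivorous fish series for its simulated
#' counterpart, a double-check mode for when the fish model is the weak
#' link).  With `noise = TRUE`, one resampled error vector per step is
#' added to every run; the ensemble mean and the 2.5/97.5 empirical
#' percentiles per year form the reported trajectory and 95\% prediction
#' band.  Predicted values are not clipped unless `clamp = TRUE`, since
#' clipping would distort threshold crossings.
#'
#' @param fit a [fit_foodweb()] result.
#' @param data dataset holding observed drivers (defaults to the fitting
#'   data).
#' @param n_runs number of Monte Carlo runs (default 1000).
#' @param seed integer seed; the same seed gives a bit-identical result.
#' @param start_year first simulated year (default: first year with a
#'   complete lag-1 record).
#' @param horizon number of annual steps (default: through the last year
#'   covered by the drivers).
#' @param noise add resampled residual vectors.
#' @param fish_observed substitute observed FIS for simulated FIS.
#' @param clamp clamp predictions to the observed range of each series.
#' @return an object of class `foodweb_sim` with per-run trajectories,
#'   ensemble mean and 95\% band per year, and the configuration echo.
#' @export
simulate_foodweb <- function(fit, data = fit$data, n_runs = 1000, seed = 1,
                             start_year = NULL, horizon = NULL,
                             noise = TRUE, fish_observed = FALSE,
                             clamp = FALSE) {
  stopifnot(inherits(fit, "foodweb_fit"))
  data <- as.data.frame(data)
  if (is.null(start_year)) start_year <- data$year[2]
  if (is.null(horizon)) horizon <- max(data$year) - start_year
  if (horizon < 1) stop("horizon must be >= 1")
  if (n_runs < 1) stop("n_runs must be >= 1")
  need_drv <- intersect(DRIVERS, names(data))
  years <- start_year + 0:horizon
  if (!all(years[-length(years)] %in% data$year))
    stop("horizon exceeds driver coverage: drivers observed through ",
         max(data$year))
  if (fish_observed && !all(years %in% data$year))
    stop("fish_observed mode needs observed FIS through ", max(years))
  obs0 <- data[data$year == start_year, BIOTIC]
  if (nrow(obs0) != 1 || any(is.na(obs0)))
    stop("start year ", start_year, " lacks a complete biotic state")
  E <- fit$residual_matrix
  rng <- if (clamp) lapply(data[BIOTIC], range, na.rm = TRUE)
  traj <- array(NA_real_, c(n_runs, horizon + 1, 4),
                dimnames = list(NULL, years, BIOTIC))
  traj[, 1, ] <- matrix(as.numeric(obs0), n_runs, 4, byrow = TRUE)
  with_seed(seed, {
    state <- traj[, 1, , drop = TRUE]
    if (n_runs == 1) state <- matrix(state, 1, 4,
                                     dimnames = list(NULL, BIOTIC))
    for (k in seq_len(horizon)) {
      yr <- years[k]
      drv <- as.list(data[data$year == yr, need_drv, drop = FALSE])
      pred <- fw_step(fit$fits, state, drv)
      if (noise) pred <- pred + resample_error_vector(E, n_runs)
      if (clamp)
        for (v in BIOTIC) pred[, v] <- pmin(pmax(pred[, v], rng[[v]][1]),
                                            rng[[v]][2])
      if (fish_observed)
        pred[, "FIS"] <- data$FIS[data$year == years[k + 1]]
      traj[, k + 1, ] <- pred
      state <- pred
    }
  })
  mean_tr <- apply(traj, c(2, 3), mean)
  lo <- apply(traj, c(2, 3), quantile, probs = 0.025, type = 7)
  hi <- apply(traj, c(2, 3), quantile, probs = 0.975, type = 7)
  out <- list(trajectories = traj, mean = mean_tr, band_low = lo,
              band_high = hi, years = years,
              config = list(n_runs = n_runs, seed = seed,
                            start_year = start_year, horizon = horizon,
                            noise = noise, fish_observed = fish_observed,
                            clamp = clamp))
  class(out) <- "foodweb_sim"
  out
}

#' @export
simulate.foodweb_fit <- function(object, nsim = 1000, seed = 1, ...) {
  simulate_foodweb(object, n_runs = nsim, seed = seed, ...)
}

#' @export
print.foodweb_sim <- function(x, ...) {
  cfg <- x$config
  cat("Food-web simulation:", cfg$n_runs, "runs,",
      cfg$start_year, "-", max(x$years),
      if (!cfg$noise) "(noise off)" else "", "\n")
  invisible(x)
}

#' @export
plot.foodweb_sim <- function(x, data = NULL, ...) {
  op <- graphics::par(mfrow = c(2, 2))
  on.exit(graphics::par(op))
  for (v in BIOTIC) {
    ylim <- range(x$band_low[, v], x$band_high[, v],
                  if (!is.null(data)) data[[v]], na.rm = TRUE)
    plot(x$years, x$mean[, v], type = "l", col = "blue", ylim = ylim,
         xlab = "year", ylab = v, ...)
    graphics::lines(x$years, x$band_low[, v], lty = 2, col = "blue")
    graphics::lines(x$years, x$band_high[, v], lty = 2, col = "blue")
    if (!is.null(data)) graphics::points(data$year, data[[v]], pch = 16,
                                         cex = 0.6)
  }
  invisible(x)
}

#' Export simulation bands as CSV
#' @param sim a [simulate_foodweb()] result.
#' @param path output CSV path.
#' @export
write_sim_bands_csv <- function(sim, path) {
  long <- do.call(rbind, lapply(BIOTIC, function(v)
    data.frame(year = sim$years, variable = v, mean = sim$mean[, v],
               band_low = sim$band_low[, v], band_high = sim$band_high[, v])))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
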