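#' Perturb a series by a percentage of its mean
#'
#' Adds `delta_pct/100 * mean(series)` to every value: a uniform additive
#' shift.  Opposite deltas against the same reference mean cancel exactly,
#' so a +15 scenario is undone by a -15 perturbation taken relative to the
#' unperturbed series.
#'
#' @param series numeric series.
#' @param delta_pct signed percentage of the reference mean.
#' @param reference_mean mean against which the percentage is taken
#'   (default: the series' own mean).
#' @return the shifted series.
#' @export
perturb_series <- function(series, delta_pct,
                           reference_mean = mean(series, na.rm = TRUE)) {
  if (length(series) == 0) stop("cannot perturb an empty series")
  if (!is.finite(reference_mean)) stop("series mean is not finite")
  series + delta_pct / 100 * reference_mean
}

#' Scenario specification
#'
#' @param target variable to perturb (e.g. `"P"` or `"FIS"`).
#' @param delta signed percentage of the series mean, |delta| <= 100.
#' @param window year range for the phase-space analysis.
#' @param mode `"driver_shift"` perturbs an external driver series before
#'   simulating; `"biotic_shift"` (FIS scenarios) perturbs the biotic
#'   series where it enters as a covariate, by running the simulation with
#'   the observed-and-shifted series substituted for its simulated values.
#'   Defaults to `"biotic_shift"` for biotic targets.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(target, delta, window = NULL, mode = NULL) {
  if (abs(delta) > 100) stop("|delta| must be <= 100 (percent of the mean)")
  if (is.null(mode))
    mode <- if (target %in% BIOTIC) "biotic_shift" else "driver_shift"
  mode <- match.arg(mode, c("driver_shift", "biotic_shift"))
  structure(list(target = target, delta = delta, window = window,
                 mode = mode),
            class = "scenario_spec")
}

#' Run a perturbation scenario
#'
#' Perturbs the target series by `delta` percent of its mean, reruns the
#' coupled simulation, and also runs the unmodified baseline under the
#' same seed so that baseline and scenario share the same error-vector
#' draws (differences are attributable to the perturbation alone).  A
#' `delta = 0` scenario is bit-identical to its baseline.
#'
#' @param fit a [fit_foodweb()] result.
#' @param scenario a [scenario_spec()].
#' @param data dataset with observed drivers (defaults to the fitting
#'   data).
#' @param ... passed to [simulate_foodweb()] (`n_runs`, `seed`,
#'   `start_year`, `horizon`, ...).
#' @return an object of class `scenario_run` with elements `baseline` and
#'   `scenario` (two [simulate_foodweb()] results) and `spec`.
#' @export
run_scenario <- function(fit, scenario, data = fit$data, ...) {
  stopifnot(inherits(scenario, "scenario_spec"))
  data <- as.data.frame(data)
  if (!scenario$target %in% names(data))
    stop("scenario target '", scenario$target, "' not in dataset")
  fish_obs <- scenario$mode == "biotic_shift"
  if (fish_obs && scenario$target != "FIS")
    stop("biotic_shift scenarios are supported for FIS only")
  mod <- data
  mod[[scenario$target]] <- perturb_series(mod[[scenario$target]],
                                           scenario$delta)
  base_sim <- simulate_foodweb(fit, data = data,
                               fish_observed = fish_obs, ...)
  scen_sim <- simulate_foodweb(fit, data = mod,
                               fish_observed = fish_obs, ...)
  out <- list(baseline = base_sim, scenario = scen_sim, spec = scenario)
  class(out) <- "scenario_run"
  out
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf("Scenario %s%+g%% (%s), %d runs, years %d-%d\n",
              x$spec$target, x$spec$delta, x$spec$mode,
              x$baseline$config$n_runs, min(x$baseline$years),
              max(x$baseline$years)))
  invisible(x)
}

#' Phase-space trajectory of a consumer--resource pair
#'
#' The ordered path of (consumer, resource) points over a year window,
#' simplified to a straight line: an ordinary least-squares fit of the
#' resource on the consumer.  A steep negative path (low resource at high
#' consumer) indicates dominant top-down control; a positive path,
#' bottom-up control.  Sign changes of the slope across scenarios diagnose
#' a change in the prevailing trophic control.
#'
#' @param consumer,resource numeric series aligned with `years`.
#' @param years year labels of the series.
#' @param window years to include (>= 3).
#' @param method `"ols"` (default) or `"chord"` (endpoint chord).
#' @return an object of class `phase_trajectory` with the point path,
#'   `slope`, `intercept` and a `degenerate` flag (constant consumer).
#' @export
phase_trajectory <- function(consumer, resource, years = seq_along(consumer),
                             window = years, method = c("ols", "chord")) {
  method <- match.arg(method)
  keep <- years %in% window
  if (sum(keep) < 3) stop("phase-space window must contain >= 3 years")
  x <- consumer[keep]
  y <- resource[keep]
  yr <- years[keep]
  ord <- order(yr)
  x <- x[ord]; y <- y[ord]; yr <- yr[ord]
  degenerate <- length(unique(x)) < 2
  if (degenerate) {
    slope <- NA_real_
    intercept <- NA_real_
  } else if (method == "ols") {
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    intercept <- mean(y) - slope * mean(x)
  } else {
    slope <- (y[length(y)] - y[1]) / (x[length(x)] - x[1])
    intercept <- y[1] - slope * x[1]
  }
  structure(list(points = data.frame(year = yr, consumer = x, resource = y),
                 slope = slope, intercept = intercept,
                 degenerate = degenerate, window = sort(window),
                 method = method),
            class = "phase_trajectory")
}

#' Phase-space trajectory from a simulation's ensemble mean
#'
#' @param sim a [simulate_foodweb()] result.
#' @param consumer,resource biotic variable names (consumer as driver,
#'   resource as response).
#' @param window years to include.
#' @param ... passed to [phase_trajectory()].
#' @export
sim_phase_trajectory <- function(sim, consumer, resource, window, ...) {
  phase_trajectory(sim$mean[, consumer], sim$mean[, resource],
                   years = sim$years, window = window, ...)
}

#' @export
print.phase_trajectory <- function(x, ...) {
  cat(sprintf("Phase trajectory over %d-%d: slope %s\n",
              min(x$points$year), max(x$points$year),
              if (x$degenerate) "undefined (constant consumer)"
              else signif(x$slope, 4)))
  invisible(x)
}

#' Compare baseline and scenario phase-space trajectories
#'
#' Reports both straight-line slopes, their difference (scenario minus
#' baseline) and whether the slope sign flips.  A trophic-control "shift"
#' is declared on a sign flip, or additionally when the absolute slope
#' difference exceeds `tolerance` (off by default).
#'
#' @param baseline,scenario [phase_trajectory()] objects over the same
#'   window.
#' @param tolerance magnitude of slope change that also counts as a shift
#'   (`Inf` disables the magnitude rule).
#' @return a list with `slope_baseline`, `slope_scenario`, `difference`,
#'   `sign_flip` and `shift`.
#' @export
compare_scenarios <- function(baseline, scenario, tolerance = Inf) {
  stopifnot(inherits(baseline, "phase_trajectory"),
            inherits(scenario, "phase_trajectory"))
  if (!identical(baseline$window, scenario$window))
    stop("trajectories cover different windows")
  if (baseline$degenerate || scenario$degenerate)
    stop("cannot compare a degenerate trajectory (constant consumer)")
  d <- scenario$slope - baseline$slope
  flip <- sign(scenario$slope) != sign(baseline$slope)
  list(slope_baseline = baseline$slope, slope_scenario = scenario$slope,
       difference = d, sign_flip = flip,
       shift = flip || (is.finite(tolerance) && abs(d) > tolerance))
}

#' Run a grid of perturbation scenarios
#'
#' Runs every (target, delta) combination, extracts the ensemble-mean
#' phase-space trajectories of the requested consumer--resource pairs over
#' the window, and tabulates slope changes against the shared-seed
#' baseline.
#'
#' @param fit a [fit_foodweb()] result.
#' @param targets variables to perturb.
#' @param deltas percentages of the mean (applied to every target).
#' @param window phase-space year window.
#' @param pairs list of `c(consumer, resource)` pairs.
#' @param ... passed to [run_scenario()] / [simulate_foodweb()].
#' @return data frame: target, delta, pair, baseline and scenario slopes,
#'   sign-flip flag.
#' @export
scenario_grid <- function(fit, targets = c("P", "FIS"),
                          deltas = c(-25, -15, 15, 25),
                          window,
                          pairs = list(c("ZOO", "PHY"), c("FIS", "ZOO")),
                          ...) {
  rows <- list()
  for (tg in targets) {
    for (d in deltas) {
      run <- run_scenario(fit, scenario_spec(tg, d, window), ...)
      for (p in pairs) {
        tb <- sim_phase_trajectory(run$baseline, p[1], p[2], window)
        ts <- sim_phase_trajectory(run$scenario, p[1], p[2], window)
        cmp <- compare_scenarios(tb, ts)
        rows[[length(rows) + 1]] <- data.frame(
          target = tg, delta = d, pair = paste(p, collapse = "/"),
          slope_baseline = cmp$slope_baseline,
          slope_scenario = cmp$slope_scenario,
          difference = cmp$difference, sign_flip = cmp$sign_flip)
      }
    }
  }
  do.call(rbind, rows)
}
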