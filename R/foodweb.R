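#' Standardize a series to zero mean and unit variance
#'
#' `(x - mean)/sd`, with the mean and sd retained so the transformation can
#' be inverted.  Standardizing an already standardized series changes
#' nothing (idempotence).
#'
#' @param x numeric series (>= 2 non-missing values).
#' @return numeric vector with attribute `record = c(mean, sd)`.
#' @export
standardize <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("need at least 2 non-missing values")
  m <- mean(x[ok])
  s <- sd(x[ok])
  if (s == 0) stop("cannot standardize a constant series (zero sd)")
  out <- (x - m) / s
  attr(out, "record") <- c(mean = m, sd = s)
  out
}

#' Invert a standardization
#' @param x standardized values.
#' @param record `c(mean, sd)` as stored by [standardize()].
#' @return values on the original scale.
#' @export
unstandardize <- function(x, record) as.numeric(x) * record["sd"] + record["mean"]

#' Lag a series by k years
#'
#' The value at year t equals the input at year t-k; the first k entries
#' are missing.  `k = 0` is disallowed: all food-web covariates enter with
#' at least one year of lag.
#'
#' @param x numeric series (assumed in year order).
#' @param k positive integer lag.
#' @return lagged numeric vector of the same length.
#' @export
lag_series <- function(x, k = 1) {
  if (k < 1) stop("lag k must be >= 1")
  n <- length(x)
  if (k >= n) {
    warning("lag k >= series length; all values missing")
    return(rep(NA_real_, n))
  }
  c(rep(NA_real_, k), x[seq_len(n - k)])
}

#' Food-web dataset
#'
#' A year-indexed table of the annual series: the four biotic series
#' (PHY, ZOO, GEL, FIS), predatory fish biomass (PRE), fishing mortality
#' (F), sea-surface temperature (SST), winter NAO index (NAO) and
#' phosphorus loading (P).  Selected columns are standardized to zero mean
#' and unit variance, with the per-series record kept for
#' back-transformation; thresholds are then searched on the scale each
#' variable enters the models.
#'
#' @param df data frame with a `year` column.
#' @param standardize `TRUE` for the default set (biotic series, PRE and
#'   SST), `FALSE` for none, or a character vector of column names.
#' @return an object of class `foodweb_data` (a data frame with a
#'   `scaling` attribute).
#' @export
foodweb_data <- function(df, standardize = TRUE) {
  df <- as.data.frame(df)
  if (!"year" %in% names(df)) stop("missing required column: year")
  if (anyDuplicated(df$year)) stop("duplicate years in dataset")
  df <- df[order(df$year), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1 && any(diff(df$year) != 1))
    warning("years are not consecutive")
  known <- c("PHY", "ZOO", "GEL", "FIS", "PRE", "F", "SST", "NAO", "P")
  unknown <- setdiff(names(df), c("year", known))
  vars <- if (isTRUE(standardize)) {
    intersect(c("PHY", "ZOO", "GEL", "FIS", "PRE", "SST"), names(df))
  } else if (is.character(standardize)) standardize else character()
  scaling <- data.frame(var = setdiff(names(df), "year"),
                        mean = 0, sd = 1, standardized = FALSE)
  for (v in vars) {
    z <- standardize(df[[v]])
    rec <- attr(z, "record")
    df[[v]] <- as.numeric(z)
    scaling[scaling$var == v, c("mean", "sd", "standardized")] <-
      list(rec["mean"], rec["sd"], TRUE)
  }
  structure(df, scaling = scaling, unknown_columns = unknown,
            class = c("foodweb_data", "data.frame"))
}

#' @export
print.foodweb_data <- function(x, ...) {
  cat("Food-web dataset:", nrow(x), "years (",
      min(x$year), "-", max(x$year), "), variables:",
      paste(setdiff(names(x), "year"), collapse = ", "), "\n")
  sc <- attr(x, "scaling")
  std <- sc$var[sc$standardized]
  if (length(std)) cat("  standardized:", paste(std, collapse = ", "), "\n")
  if (length(attr(x, "unknown_columns")))
    cat("  unrecognised columns:",
        paste(attr(x, "unknown_columns"), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a food-web dataset as CSV
#'
#' @param path CSV file with a `year` column and a subset of the standard
#'   variables.
#' @param standardize passed to [foodweb_data()] (default: no rescaling,
#'   so write/read round-trips exactly).
#' @return a [foodweb_data()] object.
#' @export
read_foodweb_csv <- function(path, standardize = FALSE) {
  df <- read.csv(path, check.names = FALSE)
  if (!"year" %in% names(df)) stop("missing required column: year")
  for (v in names(df)) {
    if (!is.numeric(df[[v]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[v]]))) &
                     !is.na(df[[v]]))
      stop("non-numeric values in column '", v, "' (row ",
           paste(head(bad, 3), collapse = ", "), ")")
    }
  }
  foodweb_data(df, standardize = standardize)
}

#' @rdname read_foodweb_csv
#' @param data a [foodweb_data()] object.
#' @export
write_foodweb_csv <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Write ground-truth metadata as a YAML sidecar
#' @param truth a [truth_spec()].
#' @param path output YAML path.
#' @export
write_truth_yaml <- function(truth, path) {
  ser_smooth <- function(s) list(type = s$type,
                                 params = unclass(s)[names(s) != "type"])
  ser_model <- function(m) list(
    intercept = m$intercept,
    low_offset = m$low_offset %||% 0,
    high_offset = m$high_offset %||% 0,
    threshold = list(kind = m$threshold$kind,
                     var = as.list(m$threshold$var),
                     value = as.list(unname(m$threshold$value)),
                     orientation = m$threshold$orientation),
    low = lapply(m$low, ser_smooth),
    high = lapply(m$high, ser_smooth),
    whole = lapply(m$whole, ser_smooth))
  obj <- list(models = lapply(truth$models, ser_model),
              noise_sd = as.list(truth$noise_sd),
              noise_correlation = apply(truth$noise_correlation, 1, as.list),
              low_fraction = as.list(truth$low_fraction))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' The four published model structures
#'
#' Returns the model structures of the four trophic-level models:
#' phytoplankton switches on lag-1 phosphorus (zooplankton grazing below
#' the threshold, NAO above, gelatinous plankton over the whole range);
#' zooplankton switches on lag-1 planktivorous fish (gelatinous plankton,
#' SST and phytoplankton below, predatory fish above); gelatinous plankton
#' switches on lag-1 fish (zooplankton below; zooplankton and phytoplankton
#' above; SST over the whole range); planktivorous fish switch on a line in
#' the lag-1 (ZOO, GEL) plane (fishing mortality below; zooplankton and NAO
#' above).  Threshold values are left to be estimated from the data; the
#' knot cap is 4.
#'
#' @return named list of four [model_structure()] objects.
#' @export
published_structures <- function() {
  list(
    PHY = model_structure("PHY", threshold_spec("P"),
                          low = "ZOO", high = "NAO", whole = "GEL"),
    ZOO = model_structure("ZOO", threshold_spec("FIS"),
                          low = c("GEL", "SST", "PHY"), high = "PRE"),
    GEL = model_structure("GEL", threshold_spec("FIS"),
                          low = "ZOO", high = c("ZOO", "PHY"),
                          whole = "SST"),
    FIS = model_structure("FIS",
                          threshold_spec(c("ZOO", "GEL"),
                                         orientation = "high_below"),
                          low = "F", high = c("ZOO", "NAO")))
}

## lag-1 model frame for one response: response at lag 0, covariates and
## threshold variables at lag 1, year retained for alignment
lagged_frame <- function(data, structure) {
  covs <- unique(c(structure$threshold$var, structure$low, structure$high,
                   structure$whole))
  lf <- data.frame(year = data$year)
  lf[[structure$response]] <- data[[structure$response]]
  covs <- setdiff(covs, structure$response)
  for (v in covs) lf[[v]] <- lag_series(data[[v]], 1)
  lf
}

#' Fit the coupled food-web models
#'
#' Fits each trophic-level model with [tgam()] on the lag-1 model frame
#' (response at year t, every covariate and threshold variable at year
#' t-1; the first year is lost to lagging and dropped case-wise).  With
#' `selection = TRUE`, [stepwise_select()] runs for each response.
#'
#' @param data a [foodweb_data()] object.
#' @param structures named list of [model_structure()]s (default
#'   [published_structures()]).
#' @param selection run backward stepwise selection per response.
#' @param min_regime_fraction passed to [tgam()].
#' @param ... passed to [tgam()].
#' @return an object of class `foodweb_fit`: per-response fits, a Table-1
#'   style summary, the aligned residual matrix used for correlated
#'   residual resampling, and residual diagnostics.
#' @export
fit_foodweb <- function(data, structures = published_structures(),
                        selection = FALSE, min_regime_fraction = 0.15,
                        ...) {
  stopifnot(inherits(data, "foodweb_data"))
  fits <- list()
  years <- list()
  for (r in names(structures)) {
    st <- structures[[r]]
    lf <- lagged_frame(data, st)
    used <- setdiff(names(lf), "year")
    keep <- complete.cases(lf[, used, drop = FALSE])
    fit <- tryCatch({
      yresp <- lf[[st$response]]
      if (sd(yresp, na.rm = TRUE) == 0)
        stop("response series is constant")
      if (selection) {
        stepwise_select(st, lf, min_regime_fraction = min_regime_fraction,
                        ...)$fit
      } else {
        tgam(st, lf, min_regime_fraction = min_regime_fraction, ...)
      }
    }, error = function(e) {
      stop("model for response '", r, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    fits[[r]] <- fit
    years[[r]] <- lf$year[keep]
  }
  common <- Reduce(intersect, years)
  resid_mat <- sapply(names(fits), function(r)
    residuals(fits[[r]])[match(common, years[[r]])])
  rownames(resid_mat) <- common
  diag_tab <- do.call(rbind, lapply(names(fits), function(r) {
    e <- residuals(fits[[r]])
    ac <- acf(e, lag.max = 3, plot = FALSE)$acf[2:4]
    sw <- shapiro.test(e)
    data.frame(response = r, acf1 = ac[1], acf2 = ac[2], acf3 = ac[3],
               shapiro_W = unname(sw$statistic), shapiro_p = sw$p.value,
               r2_adj = fits[[r]]$r2_adj, n = fits[[r]]$n)
  }))
  out <- list(fits = fits, structures = structures, data = data,
              residual_matrix = resid_mat, diagnostics = diag_tab,
              summary = foodweb_summary_table(fits))
  class(out) <- "foodweb_fit"
  out
}

## Table-1 style layout: response, regime, covariate, edf, p-value
foodweb_summary_table <- function(fits) {
  do.call(rbind, lapply(names(fits), function(r) {
    s <- summary(fits[[r]])
    if (nrow(s$terms) == 0) return(NULL)
    cbind(response = r, s$terms,
          intercept = s$intercept, gcv = s$gcv, r2_adj = s$r2_adj)
  }))
}

#' @export
print.foodweb_fit <- function(x, ...) {
  cat("Coupled food-web fit (", length(x$fits), " models )\n", sep = "")
  for (r in names(x$fits)) {
    f <- x$fits[[r]]
    th <- f$threshold
    lab <- switch(th$kind,
                  univariate = sprintf("theta(%s) = %.3f", th$var,
                                       th$value),
                  bivariate_line = sprintf(
                    "line in (%s, %s): intercept %.2f slope %.2f",
                    th$var[1], th$var[2], th$value[1], th$value[2]),
                  none = "additive")
    cat(sprintf("  %s: %s, R2(adj) = %.3f, GCV = %.4g\n",
                r, lab, f$r2_adj, f$gcv))
  }
  invisible(x)
}

#' @export
summary.foodweb_fit <- function(object, ...) object$summary

#' Export a Table-1 style fit summary as CSV
#' @param fit a [fit_foodweb()] result.
#' @param path output CSV path.
#' @export
write_fit_summary_csv <- function(fit, path) {
  write.csv(fit$summary, path, row.names = FALSE)
  invisible(path)
}
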