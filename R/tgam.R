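#' Threshold specification
#'
#' Describes how observations are split into a "low" and a "high" regime.
#' A univariate threshold assigns an observation to the low regime when the
#' threshold variable is `<=` the threshold value.  A bivariate line
#' threshold splits the plane of two variables `(v1, v2)` by the line
#' `v2 = intercept + slope * v1`; with orientation `"high_below"` (the
#' default) the high regime is the side strictly below the line, and points
#' on the line go to the low regime, mirroring the `<=` convention.
#'
#' @param var threshold variable name (length 1), or the two variable names
#'   `(v1, v2)` for a line threshold.
#' @param value threshold value, or `c(intercept, slope)` of the line;
#'   `NULL` when the threshold is to be estimated from the data.
#' @param kind `"univariate"`, `"bivariate_line"` or `"none"` (no regime
#'   switching: a fully additive model).
#' @param orientation for line thresholds, which side is the high regime.
#' @return an object of class `threshold_spec`.
#' @export
threshold_spec <- function(var = NULL, value = NULL,
                           kind = c("univariate", "bivariate_line", "none"),
                           orientation = c("high_below", "high_above")) {
  if (missing(kind)) {
    kind <- if (is.null(var)) "none"
            else if (length(var) == 2) "bivariate_line" else "univariate"
  } else kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  if (kind == "univariate" && length(var) != 1)
    stop("univariate threshold needs exactly one variable")
  if (kind == "bivariate_line" && length(var) != 2)
    stop("bivariate line threshold needs exactly two variables")
  if (kind == "none") var <- NULL
  ts <- structure(list(kind = kind, var = var, value = value,
                       orientation = orientation),
                  class = "threshold_spec")
  if (kind == "bivariate_line" && !is.null(value)) {
    if (length(value) != 2) stop("line value must be c(intercept, slope)")
    ts$angle <- atan(value[2]) * 180 / pi
    ts$uc <- value[1] * cos(atan(value[2]))
  }
  ts
}

## projection used for line thresholds: u = cos(phi) v2 - sin(phi) v1,
## the line is u = uc.  Low regime: u >= uc ("high_below") or u <= uc.
line_projection <- function(angle_deg, x1, x2) {
  phi <- angle_deg * pi / 180
  cos(phi) * x2 - sin(phi) * x1
}

#' Assign observations to regimes
#'
#' @param threshold a [threshold_spec()] with a concrete value.
#' @param newdata data frame (or named list) holding the threshold
#'   variable(s); for food-web models these are the lag-1 values.
#' @return character vector of `"low"` / `"high"` per row.
#' @examples
#' ts <- threshold_spec("P", value = 47.52)
#' assign_regime(ts, data.frame(P = c(40, 47.52, 50)))
#' @export
assign_regime <- function(threshold, newdata) {
  if (threshold$kind == "none")
    return(rep("low", nrow(as.data.frame(newdata))))
  if (is.null(threshold$value))
    stop("threshold has no value; fit or supply one")
  newdata <- as.data.frame(newdata)
  miss <- setdiff(threshold$var, names(newdata))
  if (length(miss))
    stop("missing threshold variable(s): ", paste(miss, collapse = ", "))
  if (threshold$kind == "univariate") {
    v <- newdata[[threshold$var]]
    if (any(is.na(v))) stop("missing values in threshold variable '",
                            threshold$var, "'")
    return(ifelse(v <= threshold$value, "low", "high"))
  }
  x1 <- newdata[[threshold$var[1]]]
  x2 <- newdata[[threshold$var[2]]]
  if (any(is.na(x1)) || any(is.na(x2)))
    stop("missing values in threshold variables")
  ## evaluate the line in (x1, x2) coordinates where possible so that
  ## points constructed on the line land exactly on the boundary
  if (is.finite(threshold$value[2])) {
    s <- x2 - (threshold$value[1] + threshold$value[2] * x1)
  } else {
    s <- (line_projection(threshold$angle, x1, x2) - threshold$uc) /
      max(abs(cos(threshold$angle * pi / 180)), 1e-12)
  }
  if (threshold$orientation == "high_below")
    ifelse(s >= 0, "low", "high")
  else
    ifelse(s <= 0, "low", "high")
}

#' Candidate thresholds from the data
#'
#' Midpoints between consecutive order statistics of the threshold
#' variable, truncated so that both regimes retain at least
#' `min_regime_fraction` of the observations.  Duplicated values produce no
#' zero-width candidates: the grid is strictly increasing.
#'
#' @param x threshold-variable values.
#' @param min_regime_fraction minimum fraction of observations per regime.
#' @return increasing numeric vector of candidate thresholds.
#' @export
candidate_thresholds <- function(x, min_regime_fraction = 0.15) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop("need at least 4 usable threshold-variable values")
  xs <- sort(x)
  kmin <- ceiling(min_regime_fraction * n - 1e-9)
  kmin <- max(kmin, 1L)
  ks <- seq_len(n - 1)
  keep <- ks >= kmin & (n - ks) >= kmin
  mids <- (xs[ks] + xs[ks + 1]) / 2
  width <- xs[ks + 1] - xs[ks]
  grid <- unique(mids[keep & width > 0])
  if (!length(grid))
    stop("no candidate thresholds left after truncation; ",
         "use a smaller min_regime_fraction")
  grid
}

#' Model structure for one trophic level
#'
#' Names the response, the threshold specification, and the covariates whose
#' smooth effects act in the low regime, the high regime, or over the whole
#' range of the threshold variable.  In food-web fits all covariates enter
#' at lag 1 (the lagging is done by [fit_foodweb()]); `tgam()` itself treats
#' columns of `data` at face value.
#'
#' @param response response column name.
#' @param threshold a [threshold_spec()].
#' @param low,high,whole character vectors of covariate names.
#' @param n_knots spline knots per term (2--4; capped at 4).
#' @return an object of class `model_structure`.
#' @export
model_structure <- function(response, threshold = threshold_spec(kind = "none"),
                            low = character(), high = character(),
                            whole = character(), n_knots = 4) {
  stopifnot(inherits(threshold, "threshold_spec"))
  if (anyDuplicated(low) || anyDuplicated(high) || anyDuplicated(whole))
    stop("covariate duplicated within a regime")
  if (threshold$kind == "none" && (length(low) || length(high))) {
    whole <- unique(c(whole, low, high))
    low <- high <- character()
  }
  if (response %in% c(low, high, whole))
    stop("response cannot be one of its own covariates")
  structure(list(response = response, threshold = threshold,
                 low = low, high = high, whole = whole,
                 n_knots = n_knots),
            class = "model_structure")
}

## term bookkeeping: data.frame(term, var, regime, code) ---------------------
structure_terms <- function(structure) {
  tt <- rbind(
    if (length(structure$low))
      data.frame(var = structure$low, regime = "low"),
    if (length(structure$high))
      data.frame(var = structure$high, regime = "high"),
    if (length(structure$whole))
      data.frame(var = structure$whole, regime = "whole"))
  if (is.null(tt)) return(data.frame(var = character(), regime = character(),
                                     term = character(), code = integer()))
  tt$term <- paste(tt$var, tt$regime, sep = ":")
  tt$code <- c(low = 1L, high = 2L, whole = 0L)[tt$regime]
  tt
}

## build bases + full (unmasked) design for a structure on a model frame.
## A threshold model switches between two GAMs, so each regime carries its
## own intercept: the shared `(Intercept)` column plus an unpenalized
## high-regime offset column (all ones, masked to the high regime).
tgam_design <- function(structure, mf) {
  tt <- structure_terms(structure)
  bases <- list()
  Xs <- list()
  for (i in seq_len(nrow(tt))) {
    b <- ncs_basis(mf[[tt$var[i]]], n_knots = structure$n_knots,
                   var = tt$var[i])
    bases[[tt$term[i]]] <- b
    Xs[[tt$term[i]]] <- ncs_design(b)
  }
  n <- nrow(mf)
  has_offset <- structure$threshold$kind != "none"
  X0 <- cbind(`(Intercept)` = rep(1, n),
              if (has_offset) matrix(1, n, 1,
                                     dimnames = list(NULL, "high_offset")),
              if (length(Xs)) do.call(cbind, Xs))
  ncols <- vapply(Xs, ncol, 0L)
  block <- c(rep(0L, 1 + has_offset), rep(seq_along(Xs), ncols))
  col_regime <- c(0L, if (has_offset) 2L, rep(tt$code, ncols))
  list(tt = tt, bases = bases, X0 = X0, block = block,
       col_regime = col_regime, has_offset = has_offset,
       Spen = lapply(bases, function(b) b$Sz))
}

## minimum observations a regime needs: largest basis dimension among its
## terms (regimes without terms need none)
regime_min_obs <- function(tt, bases, code) {
  dims <- vapply(tt$term[tt$code == code],
                 function(t) bases[[t]]$dim, 0L)
  if (length(dims)) max(dims) else 0L
}

#' Fit a threshold generalized additive model
#'
#' Fits the regime-switching additive model: smooth terms listed in the
#' structure's `low` (`high`) set act only on observations at or below
#' (above) the threshold, `whole`-range terms act everywhere, and a single
#' intercept is shared.  The threshold is estimated by grid search: every
#' candidate (midpoints between order statistics for a univariate
#' threshold; an (angle, intercept) grid for a line threshold) is fitted
#' with a full per-term GCV smoothing-parameter search, and the candidate
#' minimising the model GCV wins.  Ties go to the candidate nearest the
#' median of the threshold variable.  With `kind = "none"` the model is an
#' ordinary additive model and no search is run.
#'
#' @param structure a [model_structure()].
#' @param data data frame holding the response and all covariates
#'   (already lagged where that is intended).
#' @param min_regime_fraction minimum fraction of observations per regime
#'   during the threshold search.
#' @param fixed_threshold optionally a threshold value (univariate) or
#'   `list(angle, uc)` / `c(intercept, slope)` (bivariate) to skip the
#'   search.
#' @param angle_res,max_intercepts resolution of the line-threshold search:
#'   angle grid step in degrees over (-90, 90], and the maximum number of
#'   intercept candidates retained per angle (evenly thinned midpoints of
#'   the projected order statistics).
#' @return an object of class `tgam`.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(80), z = rnorm(80))
#' d$y <- ifelse(d$x <= 0, -0.8 * d$z, 0.8 * d$z) + rnorm(80, sd = 0.3)
#' st <- model_structure("y", threshold_spec("x"), low = "z", high = "z")
#' fit <- tgam(st, d)
#' fit$threshold$value
#' @export
tgam <- function(structure, data, min_regime_fraction = 0.15,
                 fixed_threshold = NULL, angle_res = 3,
                 max_intercepts = 25) {
  stopifnot(inherits(structure, "model_structure"))
  data <- as.data.frame(data)
  used <- unique(c(structure$response, structure$threshold$var,
                   structure$low, structure$high, structure$whole))
  miss <- setdiff(used, names(data))
  if (length(miss))
    stop("data is missing column(s): ", paste(miss, collapse = ", "))
  mf <- data[, used, drop = FALSE]
  keep <- complete.cases(mf)
  mf <- mf[keep, , drop = FALSE]
  n <- nrow(mf)
  if (n <= 2) stop("need more than 2 complete observations")
  y <- mf[[structure$response]]
  if (!is.numeric(y) || any(!is.finite(y)))
    stop("response '", structure$response, "' must be finite numeric")

  des <- tgam_design(structure, mf)
  kind <- structure$threshold$kind
  min_low <- max(regime_min_obs(des$tt, des$bases, 1L), 1L)
  min_high <- max(regime_min_obs(des$tt, des$bases, 2L),
                  1L + des$has_offset)

  threshold <- structure$threshold
  profile <- NULL
  if (kind == "none") {
    xthr <- rep(-Inf, n)  # everything "low"; no low/high terms exist
    theta <- 0
  } else if (kind == "univariate") {
    xthr <- mf[[threshold$var]]
    if (!is.null(fixed_threshold)) {
      theta <- fixed_threshold
    } else {
      cand <- candidate_thresholds(xthr, min_regime_fraction)
      prof <- tgam_profile_cpp(des$X0, y, des$block, des$col_regime,
                               des$Spen, xthr, cand,
                               .lam_lo, .lam_hi, .lam_grid, .lam_sweeps,
                               min_low, min_high)
      gcvs <- prof$gcv
      if (all(is.na(gcvs)))
        stop("all candidate thresholds skipped (regimes too small)")
      profile <- data.frame(theta = cand, gcv = gcvs, n_low = prof$nlow)
      theta <- pick_threshold(cand, gcvs, median(xthr))
    }
    threshold$value <- theta
  } else {  # bivariate_line
    x1 <- mf[[threshold$var[1]]]
    x2 <- mf[[threshold$var[2]]]
    if (!is.null(fixed_threshold)) {
      if (is.list(fixed_threshold)) {
        threshold$angle <- fixed_threshold$angle
        threshold$uc <- fixed_threshold$uc
      } else {
        threshold$angle <- atan(fixed_threshold[2]) * 180 / pi
        threshold$uc <- fixed_threshold[1] * cos(atan(fixed_threshold[2]))
      }
    } else {
      angles <- seq(-90 + angle_res, 90, by = angle_res)
      best <- list(gcv = Inf)
      rows <- list()
      sgn <- if (threshold$orientation == "high_below") -1 else 1
      for (a in angles) {
        u <- line_projection(a, x1, x2)
        cu <- candidate_thresholds(u, min_regime_fraction)
        if (length(cu) > max_intercepts)
          cu <- cu[unique(round(seq(1, length(cu),
                                    length.out = max_intercepts)))]
        prof <- tgam_profile_cpp(des$X0, y, des$block, des$col_regime,
                                 des$Spen, sgn * u, sgn * cu,
                                 .lam_lo, .lam_hi, .lam_grid, .lam_sweeps,
                                 min_low, min_high)
        rows[[length(rows) + 1]] <-
          data.frame(angle = a, uc = cu, gcv = prof$gcv, n_low = prof$nlow)
        if (any(is.finite(prof$gcv))) {
          uc_a <- pick_threshold(cu, prof$gcv, median(u))
          g_a <- min(prof$gcv, na.rm = TRUE)
          if (is.finite(g_a) &&
              (!is.finite(best$gcv) || g_a < best$gcv - 1e-12 * abs(best$gcv)))
            best <- list(gcv = g_a, angle = a, uc = uc_a)
        }
      }
      if (!is.finite(best$gcv))
        stop("all candidate threshold lines skipped (regimes too small)")
      profile <- do.call(rbind, rows)
      threshold$angle <- best$angle
      threshold$uc <- best$uc
    }
    if (abs(abs(threshold$angle) - 90) > 1e-8) {
      phi <- threshold$angle * pi / 180
      threshold$value <- c(intercept = threshold$uc / cos(phi),
                           slope = tan(phi))
    } else threshold$value <- c(intercept = NA_real_, slope = Inf)
  }

  ## final fit at the selected threshold
  regime <- if (kind == "none") rep("low", n) else assign_regime(threshold, mf)
  fit <- tgam_refit(des, y, regime)
  if (!isTRUE(fit$res$ok)) stop("final penalized fit failed")
  out <- pls_postprocess(fit$res, y, fit$X, des$block, des$tt$term)
  out$structure <- structure
  out$threshold <- threshold
  out$bases <- des$bases
  out$col_regime <- des$col_regime
  out$terms <- des$tt
  out$intercept <- out$beta[1]
  out$high_offset <- if (des$has_offset) out$beta[2] else 0
  out$regime <- regime
  out$profile <- profile
  out$mf <- mf
  out$min_regime_fraction <- min_regime_fraction
  out$dropped <- sum(!keep)
  class(out) <- "tgam"
  out
}

## deterministic tie-break toward the median of the threshold variable
pick_threshold <- function(cand, gcvs, med) {
  ok <- which(is.finite(gcvs))
  g <- gcvs[ok]
  gmin <- min(g)
  tied <- ok[g <= gmin + 1e-10 * max(abs(gmin), 1e-12)]
  cand[tied[which.min(abs(cand[tied] - med))]]
}

## mask the full design by regime and solve at (searched) lambdas
tgam_refit <- function(des, y, regime) {
  X <- des$X0
  low <- regime == "low"
  if (any(des$col_regime == 1L)) X[!low, des$col_regime == 1L] <- 0
  if (any(des$col_regime == 2L)) X[low, des$col_regime == 2L] <- 0
  res <- pls_fit_cpp(X, y, des$block, des$Spen, NULL,
                     .lam_lo, .lam_hi, .lam_grid, .lam_sweeps)
  list(res = res, X = X)
}

#' @export
predict.tgam <- function(object, newdata = NULL, type = c("response", "terms"),
                         ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$mf
  newdata <- as.data.frame(newdata)
  tt <- object$terms
  need <- unique(c(tt$var, object$threshold$var))
  miss <- setdiff(need, names(newdata))
  if (length(miss))
    stop("newdata is missing covariate(s): ", paste(miss, collapse = ", "))
  n <- nrow(newdata)
  regime <- if (object$threshold$kind == "none") rep("low", n)
            else assign_regime(object$threshold, newdata)
  J <- nrow(tt)
  terms_mat <- matrix(0, n, J, dimnames = list(NULL, tt$term))
  for (j in seq_len(J)) {
    cols <- which(object$block == j)
    val <- drop(ncs_design(object$bases[[tt$term[j]]],
                           newdata[[tt$var[j]]]) %*% object$beta[cols])
    if (tt$code[j] == 1L) val[regime != "low"] <- 0
    if (tt$code[j] == 2L) val[regime == "low"] <- 0
    terms_mat[, j] <- val
  }
  if (type == "terms") return(terms_mat)
  object$intercept + object$high_offset * (regime == "high") +
    if (J > 0) rowSums(terms_mat) else 0
}

#' @export
residuals.tgam <- function(object, ...) object$residuals

#' @export
coef.tgam <- function(object, ...) {
  nm <- "(Intercept)"
  if (object$threshold$kind != "none") nm <- c(nm, "high_offset")
  for (j in seq_len(nrow(object$terms))) {
    k <- sum(object$block == j)
    nm <- c(nm, paste0(object$terms$term[j], ".", seq_len(k)))
  }
  setNames(object$beta, nm)
}

#' @export
print.tgam <- function(x, ...) {
  cat("Threshold GAM:", x$structure$response, "\n")
  th <- x$threshold
  if (th$kind == "univariate") {
    cat("  threshold on", th$var, ": theta =", signif(th$value, 4),
        sprintf(" (%d low / %d high)\n", sum(x$regime == "low"),
                sum(x$regime == "high")))
  } else if (th$kind == "bivariate_line") {
    cat(sprintf("  threshold line in (%s, %s): intercept %.3f, slope %.3f\n",
                th$var[1], th$var[2], th$value[1], th$value[2]))
  } else cat("  no threshold (fully additive)\n")
  cat("  GCV =", signif(x$gcv, 5), " R2(adj) =", signif(x$r2_adj, 3),
      " n =", x$n, "\n")
  invisible(x)
}

#' @export
summary.tgam <- function(object, ...) {
  tt <- object$terms
  tab <- data.frame(
    regime = tt$regime, covariate = tt$var,
    edf = as.numeric(object$edf),
    p_value = vapply(tt$term, function(t) term_p_value(object, t), 0),
    row.names = NULL)
  out <- list(response = object$structure$response,
              threshold = object$threshold, terms = tab,
              intercept = object$intercept, gcv = object$gcv,
              r2_adj = object$r2_adj, n = object$n)
  class(out) <- "summary.tgam"
  out
}

#' @export
print.summary.tgam <- function(x, ...) {
  cat("Response:", x$response, "\n")
  th <- x$threshold
  if (th$kind == "univariate")
    cat("Threshold (theta)", signif(th$value, 4), "on", th$var, "\n")
  if (th$kind == "bivariate_line")
    cat(sprintf("Threshold line (intercept: %.3f, slope: %.3f) in (%s, %s)\n",
                th$value[1], th$value[2], th$var[1], th$var[2]))
  cat("Intercept:", signif(x$intercept, 4), "\n")
  print(x$terms, digits = 4)
  cat("GCV =", signif(x$gcv, 5), " R2(adj) =", signif(x$r2_adj, 3),
      " n =", x$n, "\n")
  invisible(x)
}

#' @export
plot.tgam <- function(x, ...) {
  tt <- x$terms
  J <- nrow(tt)
  if (J == 0) return(invisible(x))
  op <- graphics::par(mfrow = grDevices::n2mfrow(J))
  on.exit(graphics::par(op))
  colmap <- c(low = "black", high = "red", whole = "blue")
  for (j in seq_len(J)) {
    b <- x$bases[[tt$term[j]]]
    xx <- seq(min(b$x), max(b$x), length.out = 100)
    cols <- which(x$block == j)
    yy <- drop(ncs_design(b, xx) %*% x$beta[cols])
    plot(xx, yy, type = "l", col = colmap[tt$regime[j]], xlab = b$var,
         ylab = sprintf("s(%s, %.2f) [%s]", b$var, x$edf[j], tt$regime[j]),
         ...)
    graphics::rug(b$x)
  }
  invisible(x)
}
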