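#' Genuine leave-one-out cross-validation
#'
#' Average squared leave-one-out prediction error of the *entire* fitting
#' procedure: for each left-out observation the model is refit on the
#' remaining data — including, for threshold models, a full re-search of
#' the threshold (and of all smoothing parameters) — and the left-out
#' response is predicted.  GCV does not account for the extra flexibility
#' bought by the threshold grid search; genuine CV does, which is why it is
#' the honest yardstick for comparing threshold and fully additive models.
#' `refit_threshold = FALSE` reproduces the cheaper variant that keeps the
#' full-data threshold fixed across folds.
#'
#' @param structure a [model_structure()].
#' @param data data frame with response and covariates.
#' @param refit_threshold re-search the threshold within each fold
#'   (default; the honest variant).
#' @param min_regime_fraction passed to [tgam()].
#' @param ... further arguments passed to [tgam()].
#' @return the mean squared leave-one-out prediction error, with attributes
#'   `fold_errors` (squared error per fold, `NA` for failed folds) and
#'   `n_failed`.  More than 10\% failed folds is an error.
#' @export
genuine_cv <- function(structure, data, refit_threshold = TRUE,
                       min_regime_fraction = 0.15, ...) {
  data <- as.data.frame(data)
  used <- unique(c(structure$response, structure$threshold$var,
                   structure$low, structure$high, structure$whole))
  miss <- setdiff(used, names(data))
  if (length(miss))
    stop("data is missing column(s): ", paste(miss, collapse = ", "))
  cc <- complete.cases(data[, used, drop = FALSE])
  data <- data[cc, , drop = FALSE]
  n <- nrow(data)
  if (n < 10) stop("genuine CV needs at least 10 complete observations")
  fixed <- NULL
  if (!refit_threshold && structure$threshold$kind != "none") {
    full <- tgam(structure, data, min_regime_fraction = min_regime_fraction,
                 ...)
    fixed <- if (structure$threshold$kind == "univariate")
      full$threshold$value
    else list(angle = full$threshold$angle, uc = full$threshold$uc)
  }
  errs <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    errs[i] <- tryCatch({
      fit <- tgam(structure, data[-i, , drop = FALSE],
                  min_regime_fraction = min_regime_fraction,
                  fixed_threshold = fixed, ...)
      pred <- predict(fit, data[i, , drop = FALSE])
      (data[[structure$response]][i] - pred)^2
    }, error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(errs))
  if (n_failed > 0.1 * n)
    stop("genuine CV: ", n_failed, " of ", n, " folds failed to fit")
  out <- mean(errs, na.rm = TRUE)
  attr(out, "fold_errors") <- errs
  attr(out, "n_failed") <- n_failed
  out
}

#' Compare an additive and a threshold model by genuine CV
#'
#' Computes the genuine leave-one-out CV score of both specifications on
#' the same data and selects the lower.  Per-fold squared errors are
#' retained in the report.
#'
#' @param additive a [model_structure()] without threshold (or any
#'   structure to use as the reference model).
#' @param threshold a [model_structure()] with a threshold.
#' @param data data frame.
#' @param ... passed to [genuine_cv()].
#' @return an object of class `model_comparison` with elements `cv_additive`,
#'   `cv_threshold`, `selected` (`"GAM"` or `"TGAM"`), `tie`, and the
#'   per-fold errors.
#' @export
compare_models <- function(additive, threshold, data, ...) {
  if (additive$response != threshold$response)
    stop("both structures must model the same response")
  cva <- genuine_cv(additive, data, ...)
  cvt <- genuine_cv(threshold, data, ...)
  tie <- isTRUE(all.equal(as.numeric(cva), as.numeric(cvt),
                          tolerance = 1e-12))
  out <- list(cv_additive = as.numeric(cva), cv_threshold = as.numeric(cvt),
              folds_additive = attr(cva, "fold_errors"),
              folds_threshold = attr(cvt, "fold_errors"),
              tie = tie,
              selected = if (tie) "tie"
                         else if (cvt < cva) "TGAM" else "GAM")
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Genuine leave-one-out CV comparison\n")
  cat(sprintf("  additive (GAM):  %.6g\n", x$cv_additive))
  cat(sprintf("  threshold (TGAM): %.6g\n", x$cv_threshold))
  cat("  selected:", x$selected, if (x$tie) "(tie)" else "", "\n")
  invisible(x)
}

#' Stepwise covariate selection
#'
#' Backward selection mirroring the two-criteria rule used for the
#' trophic-level models: covariates with p > `alpha` are removed one at a
#' time (worst p-value first, refitting after each drop) until every
#' remaining term has p <= `alpha` or only the intercept remains; a second
#' pass then greedily removes any term whose removal still lowers the
#' model GCV.  The significance rule leads because GCV's parsimony penalty
#' is weak: on its own it retains roughly one in four pure-noise
#' covariates.  The full drop path is returned.
#'
#' @param structure a [model_structure()].
#' @param data data frame.
#' @param alpha p-value threshold for removal (default 0.05).
#' @param ... passed to [tgam()].
#' @return list with `structure` (reduced), `fit` (final [tgam()] fit) and
#'   `path` (data frame logging each attempted drop).
#' @export
stepwise_select <- function(structure, data, alpha = 0.05, ...) {
  cur <- structure
  fit <- tgam(cur, data, ...)
  path <- data.frame(step = integer(), rule = character(),
                     dropped = character(), p_value = numeric(),
                     gcv_before = numeric(), gcv_after = numeric(),
                     accepted = logical())
  step <- 0L
  ## pass 1: significance-driven backward elimination
  repeat {
    tt <- fit$terms
    if (nrow(tt) == 0) break
    ps <- vapply(tt$term, function(t) term_p_value(fit, t), 0)
    worst <- which.max(ps)
    if (ps[worst] <= alpha) break
    trial <- drop_term(cur, tt$var[worst], tt$regime[worst])
    tfit <- tgam(trial, data, ...)
    step <- step + 1L
    path <- rbind(path, data.frame(
      step = step, rule = "p_value", dropped = tt$term[worst],
      p_value = ps[worst], gcv_before = fit$gcv, gcv_after = tfit$gcv,
      accepted = TRUE))
    cur <- trial
    fit <- tfit
  }
  ## pass 2: greedy GCV minimization over the survivors
  repeat {
    tt <- fit$terms
    if (nrow(tt) == 0) break
    trials <- lapply(seq_len(nrow(tt)), function(i)
      tgam(drop_term(cur, tt$var[i], tt$regime[i]), data, ...))
    gcvs <- vapply(trials, function(f) f$gcv, 0)
    best <- which.min(gcvs)
    if (gcvs[best] >= fit$gcv) break
    step <- step + 1L
    path <- rbind(path, data.frame(
      step = step, rule = "gcv", dropped = tt$term[best],
      p_value = NA_real_, gcv_before = fit$gcv, gcv_after = gcvs[best],
      accepted = TRUE))
    cur <- drop_term(cur, tt$var[best], tt$regime[best])
    fit <- trials[[best]]
  }
  list(structure = cur, fit = fit, path = path)
}

drop_term <- function(structure, var, regime) {
  structure[[regime]] <- setdiff(structure[[regime]], var)
  structure
}
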