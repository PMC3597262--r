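#' Natural cubic regression spline basis
#'
#' Builds a natural cubic regression spline basis for one covariate, with
#' knots placed at evenly spaced quantiles of the observed values (always
#' including the minimum and maximum).  The basis is parameterised by the
#' function values at the knots (a "cardinal" parameterisation): column
#' \eqn{j} of the evaluated basis is the natural cubic spline that is 1 at
#' knot \eqn{j} and 0 at the others.  Second derivatives at the boundary
#' knots are zero, so the fitted curve continues linearly outside the range
#' of the data.  The number of knots is capped at four to keep the fitted
#' smooths parsimonious on short annual series.
#'
#' The object also carries the second-derivative penalty matrix
#' \eqn{S = Q R^{-1} Q'} such that \eqn{g' S g = \int f''(x)^2 dx} for the
#' spline with knot values \eqn{g}, and a centering reparameterisation
#' \eqn{g = Z u} that absorbs the sum-to-zero identifiability constraint
#' over the training observations.
#'
#' @param x numeric covariate values (training data; stored in the object).
#' @param n_knots number of knots, between 2 and 4.
#' @param var covariate name used in designs and error messages.
#' @return an object of class `ncs_basis` with elements `var`, `knots`,
#'   `Gamma` (map from knot values to knot second derivatives), `S`
#'   (penalty), `Z` (constraint null-space basis), `Sz` (penalty in the
#'   constrained parameterisation), `x` (training values) and `dim`
#'   (number of knots).
#' @examples
#' b <- ncs_basis(seq(0, 1, length.out = 20), n_knots = 4, var = "x")
#' B <- ncs_eval(b, c(0.1, 0.5, 1.2))
#' @export
ncs_basis <- function(x, n_knots = 4, var = "x") {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("covariate '", var, "' must be finite numeric")
  if (!(n_knots %in% 2:4))
    stop("n_knots must be 2, 3 or 4 (got ", n_knots, ")")
  if (length(unique(x)) < n_knots)
    stop("covariate '", var, "' has fewer than ", n_knots,
         " distinct values")
  knots <- unname(quantile(x, probs = seq(0, 1, length.out = n_knots),
                           type = 7))
  knots <- unique(knots)
  if (length(knots) < n_knots)
    stop("quantile knots for '", var, "' are not distinct; ",
         "reduce n_knots")
  K <- length(knots)
  h <- diff(knots)
  if (K >= 3) {
    Q <- matrix(0, K, K - 2)
    R <- matrix(0, K - 2, K - 2)
    for (j in seq_len(K - 2)) {
      Q[j, j] <- 1 / h[j]
      Q[j + 1, j] <- -1 / h[j] - 1 / h[j + 1]
      Q[j + 2, j] <- 1 / h[j + 1]
      R[j, j] <- (h[j] + h[j + 1]) / 3
      if (j < K - 2) R[j, j + 1] <- R[j + 1, j] <- h[j + 1] / 6
    }
    Gamma <- rbind(0, solve(R, t(Q)), 0)
    S <- Q %*% solve(R, t(Q))
  } else {
    Gamma <- matrix(0, K, K)
    S <- matrix(0, K, K)
  }
  b <- structure(list(var = var, knots = knots, h = h, Gamma = Gamma,
                      S = S, x = x, dim = K),
                 class = "ncs_basis")
  ## sum-to-zero constraint over the training data
  B <- ncs_eval(b, x)
  cvec <- colSums(B)
  Z <- qr.Q(qr(matrix(cvec, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
  b$Z <- Z
  b$Sz <- t(Z) %*% S %*% Z
  b$Sz <- (b$Sz + t(b$Sz)) / 2
  b
}

#' Evaluate a natural cubic spline basis
#'
#' Evaluates the cardinal basis (or its second derivative) at arbitrary
#' covariate values.  Values outside the boundary knots are evaluated on the
#' tangent line at the nearest boundary knot (`deriv = 0`) or return zero
#' (`deriv = 2`), which is the natural boundary condition.
#'
#' @param basis an [ncs_basis()] object.
#' @param x numeric values at which to evaluate.
#' @param deriv 0 for function values, 2 for second derivatives.
#' @return a `length(x)` by `basis$dim` matrix.
#' @export
ncs_eval <- function(basis, x, deriv = 0) {
  t <- basis$knots
  K <- basis$dim
  h <- basis$h
  G <- basis$Gamma
  n <- length(x)
  M <- matrix(0, n, K)
  if (n == 0L) return(M)
  i <- findInterval(x, t)
  i <- pmin(pmax(i, 1L), K - 1L)
  left <- x < t[1]
  right <- x > t[K]
  mid <- !(left | right)
  if (deriv == 2) {
    if (any(mid)) {
      im <- i[mid]
      A <- (t[im + 1] - x[mid]) / h[im]
      B <- (x[mid] - t[im]) / h[im]
      M[mid, ] <- A * G[im, , drop = FALSE] + B * G[im + 1, , drop = FALSE]
    }
    return(M)
  }
  if (any(mid)) {
    im <- i[mid]
    A <- (t[im + 1] - x[mid]) / h[im]
    B <- (x[mid] - t[im]) / h[im]
    Cc <- (A^3 - A) * h[im]^2 / 6
    Dd <- (B^3 - B) * h[im]^2 / 6
    W <- matrix(0, sum(mid), K)
    W[cbind(seq_len(sum(mid)), im)] <- A
    W[cbind(seq_len(sum(mid)), im + 1)] <- W[cbind(seq_len(sum(mid)), im + 1)] + B
    M[mid, ] <- W + Cc * G[im, , drop = FALSE] + Dd * G[im + 1, , drop = FALSE]
  }
  if (any(left)) {
    e1 <- c(1, rep(0, K - 1))
    e2 <- c(0, 1, rep(0, K - 2))
    slope <- (e2 - e1) / h[1] - (h[1] / 6) * G[2, ]
    M[left, ] <- outer(rep(1, sum(left)), e1) + outer(x[left] - t[1], slope)
  }
  if (any(right)) {
    eK <- c(rep(0, K - 1), 1)
    eK1 <- c(rep(0, K - 2), 1, 0)
    slope <- (eK - eK1) / h[K - 1] + (h[K - 1] / 6) * G[K - 1, ]
    M[right, ] <- outer(rep(1, sum(right)), eK) + outer(x[right] - t[K], slope)
  }
  M
}

## constrained (centered) design columns for one term
ncs_design <- function(basis, x = basis$x) {
  ncs_eval(basis, x) %*% basis$Z
}

#' @export
print.ncs_basis <- function(x, ...) {
  cat("Natural cubic spline basis for '", x$var, "': ", x$dim,
      " knots at ", paste(signif(x$knots, 4), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
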