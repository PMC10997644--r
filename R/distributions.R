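#' Mixture parameter vector
#'
#' Bundles the parameter vector \eqn{\Theta = (\lambda_1, \lambda_2,
#' \lambda_3, p_1, p_2)} of the 3-component mixture of power distributions.
#' The third mixing weight is implied, \eqn{p_3 = 1 - p_1 - p_2}.
#'
#' @param lambda1,lambda2,lambda3 Positive shape parameters of the three
#'   power components, \eqn{f_m(y) = \lambda_m y^{\lambda_m - 1}} on (0, 1).
#' @param p1,p2 Mixing weights in (0, 1) with `p1 + p2 < 1`.
#' @return An object of class `mixture_params`.
#' @examples
#' mixture_params(0.4, 0.3, 0.2, 0.5, 0.3)
#' @export
mixture_params <- function(lambda1, lambda2, lambda3, p1, p2) {
  lam <- c(lambda1, lambda2, lambda3)
  stopifnot(length(lam) == 3, is.numeric(lam), is.numeric(p1), is.numeric(p2))
  if (any(!is.finite(lam)) || any(lam <= 0))
    stop("component shapes lambda_m must be positive and finite")
  if (!is.finite(p1) || !is.finite(p2) || p1 <= 0 || p2 <= 0 || p1 + p2 >= 1)
    stop("mixing weights must satisfy p1 > 0, p2 > 0, p1 + p2 < 1")
  structure(list(lambda = lam, p = c(p1, p2, 1 - p1 - p2)),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat("3-component power mixture parameters\n")
  cat(sprintf("  lambda: %s\n", paste(format(x$lambda), collapse = ", ")))
  cat(sprintf("  p:      %s\n", paste(format(x$p), collapse = ", ")))
  invisible(x)
}

#' Power distribution on the unit interval
#'
#' Density, distribution function, quantile function and random generation
#' for the power distribution with shape `lambda`:
#' \eqn{f(y) = \lambda y^{\lambda - 1}}, \eqn{F(y) = y^\lambda}, 0 < y < 1.
#'
#' @param y,q,p Vector of values / quantiles / probabilities.
#' @param lambda Positive shape parameter.
#' @param n Number of draws.
#' @return Numeric vector.
#' @examples
#' ppower(0.5, 1)   # uniform special case: 0.5
#' @name power_dist
NULL

#' @rdname power_dist
#' @export
dpower <- function(y, lambda) {
  stopifnot(lambda > 0)
  ifelse(y > 0 & y < 1, lambda * y^(lambda - 1), 0)
}

#' @rdname power_dist
#' @export
ppower <- function(q, lambda) {
  stopifnot(lambda > 0)
  pmin(1, pmax(0, q))^lambda
}

#' @rdname power_dist
#' @export
qpower <- function(p, lambda) {
  stopifnot(lambda > 0, all(p >= 0 & p <= 1))
  p^(1 / lambda)
}

#' @rdname power_dist
#' @export
rpower <- function(n, lambda) {
  qpower(runif(n), lambda)
}

#' Mixture density and survival function
#'
#' `dcmpd3()` evaluates the mixture density and `scmpd3()` the mixture
#' survival function \eqn{S(y) = \sum_m p_m (1 - y^{\lambda_m})}.
#'
#' @param y Evaluation points in (0, 1) (values outside give 0 density;
#'   survival is clamped to \[0, 1\]).
#' @param params A [mixture_params()] object.
#' @return Numeric vector.
#' @export
dcmpd3 <- function(y, params) {
  stopifnot(inherits(params, "mixture_params"))
  out <- numeric(length(y))
  for (m in 1:3) out <- out + params$p[m] * dpower(y, params$lambda[m])
  out
}

#' @rdname dcmpd3
#' @export
scmpd3 <- function(y, params) {
  stopifnot(inherits(params, "mixture_params"))
  out <- numeric(length(y))
  for (m in 1:3) out <- out + params$p[m] * (1 - ppower(y, params$lambda[m]))
  out
}
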