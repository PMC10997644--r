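# Signed log-sum-exp over the alternating binomial expansion.
#
# The (-1)^i factors make the component weights cancel; summing positive and
# negative buckets separately in the scale of the larger bucket keeps the
# subtraction as accurate as double precision allows.  If more than `guard`
# natural-log units (~13 decimal digits at the default 30) are lost to
# cancellation the result is numerically meaningless and we stop instead of
# returning garbage.
signed_logsumexp <- function(log_abs, sign, guard = 30, what = "signed sum") {
  stopifnot(length(log_abs) == length(sign))
  M <- max(log_abs)
  if (!is.finite(M)) stop("non-finite weights in ", what)
  pos <- sum(exp(log_abs[sign > 0] - M))
  neg <- sum(exp(log_abs[sign < 0] - M))
  diff <- pos - neg
  lmax <- M + log(max(pos, neg))
  if (diff == 0 || lmax - (M + log(abs(diff))) > guard)
    stop("catastrophic cancellation in ", what,
         ": more than ~13 significant digits lost; ",
         "the alternating expansion is not representable in double precision")
  list(log = M + log(abs(diff)), sign = if (diff > 0) 1 else -1)
}

#' Build the exact signed-mixture posterior
#'
#' Expands the censored factor \eqn{\{S(t)\}^{n-u}} of the likelihood by
#' nested binomial series, yielding one posterior component per index triple
#' \eqn{0 \le k \le j \le i \le n-u}.  Each component is an independent
#' product Gamma\eqn{(A_1, B_1) \times} Gamma\eqn{(A_2, B_2) \times}
#' Gamma\eqn{(A_3, B_3) \times} Dirichlet\eqn{(A_0, B_0, C_0)} carrying a
#' signed weight \eqn{(-1)^i \binom{n-u}{i}\binom{i}{j}\binom{j}{k}} times
#' the component's normalizing constant.  The constants are
#' \deqn{A_m = u_m + \delta_m, \quad
#'       B_1 = (i-j)\ln(1/t) + S_1 + b_1, \quad
#'       B_2 = (j-k)\ln(1/t) + S_2 + b_2, \quad
#'       B_3 = k\ln(1/t) + S_3 + b_3,}
#' \deqn{A_0 = i - j + u_1 + \delta_0, \quad B_0 = j - k + u_2 + \delta_0',
#'       \quad C_0 = k + u_3 + \delta_0'',}
#' where \eqn{\delta_m = 1, \delta_0 = 1, b_m = 0} under the uniform prior;
#' \eqn{\delta_m = 0} under Jeffreys' prior; and \eqn{\delta_m = a_m},
#' \eqn{b_m}, \eqn{(\delta_0, \delta_0', \delta_0'') = (a, b, c)} under the
#' informative prior.  The normalizer \eqn{\Omega} is the signed sum of the
#' absolute weights, accumulated in log space with a cancellation guard.
#'
#' @param summary A [censored_summary()].
#' @param prior A [prior_spec()] (or a family string accepted by it).
#' @return An object of class `cmpd3_posterior`: a list with `components`
#'   (data frame of indices, signs, log absolute weights, and the
#'   gamma/Dirichlet constants), `log_omega`, `prior`, and `summary`.
#' @section Errors:
#' Jeffreys' prior requires at least one observed failure per component
#' (otherwise a gamma shape is zero); any component rate \eqn{B_m \le 0}
#' (e.g. \eqn{u_m = 0} with no censoring and no informative rate) makes the
#' posterior improper; and a normalizer that is nonpositive or has lost more
#' than ~13 significant digits to cancellation raises a numerical-failure
#' error naming \eqn{n-u}.
#' @examples
#' post <- build_posterior(kevlar_summary(), "uniform")
#' nrow(post$components)  # choose(11 + 3, 3) = 364
#' @export
build_posterior <- function(summary, prior = "uniform") {
  stopifnot(inherits(summary, "censored_summary"))
  prior <- as_prior_spec(prior)
  u <- summary$u
  S <- summary$S
  L <- summary$log_inv_t
  nu <- summary$n - sum(u)

  if (prior$family == "jeffreys" && any(u < 1))
    stop("Jeffreys' prior requires at least one observed failure in every ",
         "component (u_m >= 1); got u = (", paste(u, collapse = ", "), ")")
  if (prior$family == "informative") {
    h <- unclass(prior$hyper)
    shape <- u + h[c("a1", "a2", "a3")]
    rate0 <- S + h[c("b1", "b2", "b3")]
    dir0 <- h[c("a", "b", "c")]
  } else {
    shape <- u + if (prior$family == "uniform") 1 else 0
    rate0 <- S
    dir0 <- c(1, 1, 1)
  }

  idx <- expand.grid(k = 0:nu, j = 0:nu, i = 0:nu)
  idx <- idx[idx$k <= idx$j & idx$j <= idx$i, c("i", "j", "k")]
  i <- idx$i; j <- idx$j; k <- idx$k

  B1 <- (i - j) * L + rate0[[1]]
  B2 <- (j - k) * L + rate0[[2]]
  B3 <- k * L + rate0[[3]]
  if (any(B1 <= 0) || any(B2 <= 0) || any(B3 <= 0))
    stop("improper posterior: a gamma rate B_m is not positive ",
         "(component with no observed failures, no censoring exposure, ",
         "and no informative rate)")
  A0 <- i - j + u[1] + dir0[[1]]
  B0 <- j - k + u[2] + dir0[[2]]
  C0 <- k + u[3] + dir0[[3]]

  log_abs <- lchoose(nu, i) + lchoose(i, j) + lchoose(j, k) +
    lgamma(shape[[1]]) - shape[[1]] * log(B1) +
    lgamma(shape[[2]]) - shape[[2]] * log(B2) +
    lgamma(shape[[3]]) - shape[[3]] * log(B3) +
    lgamma(A0) + lgamma(B0) + lgamma(C0) - lgamma(A0 + B0 + C0)
  sgn <- ifelse(i %% 2 == 0, 1, -1)

  omega <- tryCatch(
    signed_logsumexp(log_abs, sgn, what = "the posterior normalizer Omega"),
    error = function(e) stop(conditionMessage(e), " (n - u = ", nu, ")",
                             call. = FALSE))
  if (omega$sign <= 0)
    stop("improper posterior: Omega <= 0 (n - u = ", nu, ")")

  structure(list(
    components = data.frame(i = i, j = j, k = k, sign = sgn,
                            log_abs_weight = log_abs,
                            A1 = shape[[1]], A2 = shape[[2]], A3 = shape[[3]],
                            B1 = B1, B2 = B2, B3 = B3,
                            A0 = A0, B0 = B0, C0 = C0),
    log_omega = omega$log,
    prior = prior,
    summary = summary), class = "cmpd3_posterior")
}

#' @export
print.cmpd3_posterior <- function(x, ...) {
  cat(sprintf("Exact signed-mixture posterior (%s prior)\n", x$prior$family))
  cat(sprintf("  %d components (n - u = %d), ln(Omega) = %.6g\n",
              nrow(x$components), x$summary$n - sum(x$summary$u), x$log_omega))
  means <- vapply(c("lambda1", "lambda2", "lambda3", "p1", "p2"),
                  function(p) posterior_moment(x, p, 1), 0)
  cat("  posterior means:\n")
  print(round(means, 6))
  invisible(x)
}

param_names <- c("lambda1", "lambda2", "lambda3", "p1", "p2")

#' Posterior moments
#'
#' `posterior_moment()` returns \eqn{E(\theta^r)} for any parameter of the
#' mixture and any real order `r` for which the moment exists in every
#' mixture component.  For the shapes the per-component factor is
#' \eqn{\Gamma(A_m + r)/\Gamma(A_m) \, B_m^{-r}}; for the weights it is the
#' Dirichlet moment \eqn{B(\alpha + r, \beta)/B(\alpha, \beta)} with
#' \eqn{\alpha} the matching exponent and \eqn{\beta} the sum of the other
#' two.  `posterior_moment_lambda()` and `posterior_moment_proportion()` are
#' index-based equivalents.
#'
#' @param post A [build_posterior()] result.
#' @param param One of `"lambda1"`, `"lambda2"`, `"lambda3"`, `"p1"`,
#'   `"p2"`, `"p3"`.
#' @param r Real moment order (`r = 0` returns exactly 1).
#' @param m,s Component index 1-3 (for `p3`, `s = 3` addresses
#'   \eqn{1 - p_1 - p_2}).
#' @return A single numeric value.
#' @export
posterior_moment <- function(post, param, r) {
  stopifnot(inherits(post, "cmpd3_posterior"), length(r) == 1, is.finite(r))
  if (r == 0) return(1)
  cmp <- post$components
  if (param %in% c("lambda1", "lambda2", "lambda3")) {
    m <- match(param, c("lambda1", "lambda2", "lambda3"))
    A <- cmp[[paste0("A", m)]]
    B <- cmp[[paste0("B", m)]]
    if (min(A) + r <= 0)
      stop(sprintf(paste0("moment of order %g for %s does not exist: needs ",
                          "gamma shape > %g but the minimum shape is %g"),
                   r, param, -r, min(A)))
    extra <- lgamma(A + r) - lgamma(A) - r * log(B)
  } else {
    s <- match(param, c("p1", "p2", "p3"))
    if (is.na(s)) stop("unknown parameter: ", param)
    alpha <- switch(s, cmp$A0, cmp$B0, cmp$C0)
    if (min(alpha) + r <= 0)
      stop(sprintf(paste0("moment of order %g for %s does not exist: needs ",
                          "Dirichlet exponent > %g but the minimum is %g"),
                   r, param, -r, min(alpha)))
    tot <- cmp$A0 + cmp$B0 + cmp$C0
    extra <- lgamma(alpha + r) - lgamma(alpha) + lgamma(tot) - lgamma(tot + r)
  }
  num <- signed_logsumexp(cmp$log_abs_weight + extra, cmp$sign,
                          what = sprintf("E(%s^%g)", param, r))
  val <- num$sign * exp(num$log - post$log_omega)
  # support check: a moment of a positive quantity is positive, and a
  # positive-order moment of a probability lies in (0, 1).  Violations mean
  # the alternating sum lost its significant digits without tripping the
  # log-space guard (the absolute error of the log-weights themselves can
  # dominate for very large counts), so fail loudly rather than return them.
  bad <- val <= 0 ||
    (startsWith(param, "p") && r >= 1 && val >= 1)
  if (bad)
    stop(sprintf(paste0("numerical failure: E(%s^%g) = %g is outside the ",
                        "parameter support; the signed expansion is not ",
                        "trustworthy for this summary (n - u = %d)"),
                 param, r, val, post$summary$n - sum(post$summary$u)))
  val
}

#' @rdname posterior_moment
#' @export
posterior_moment_lambda <- function(post, m, r) {
  stopifnot(m %in% 1:3)
  posterior_moment(post, paste0("lambda", m), r)
}

#' @rdname posterior_moment
#' @export
posterior_moment_proportion <- function(post, s, r) {
  stopifnot(s %in% 1:3)
  posterior_moment(post, paste0("p", s), r)
}

#' Marginal posterior density
#'
#' The marginal posterior of each shape is a signed mixture of
#' Gamma\eqn{(A_m, B_m)} densities and that of each mixing weight a signed
#' mixture of beta densities (\eqn{p_1 \sim} Beta\eqn{(A_0, B_0 + C_0)},
#' \eqn{p_2 \sim} Beta\eqn{(B_0, A_0 + C_0)} within each component), with
#' the normalized signed weights.
#'
#' @inheritParams posterior_moment
#' @param x Evaluation points: positive reals for the shapes, (0, 1) for the
#'   weights.
#' @return Numeric vector of densities (nonnegative for a proper posterior).
#' @export
marginal_pdf <- function(post, param, x) {
  stopifnot(inherits(post, "cmpd3_posterior"))
  cmp <- post$components
  w <- cmp$sign * exp(cmp$log_abs_weight - post$log_omega)
  if (param %in% c("lambda1", "lambda2", "lambda3")) {
    m <- match(param, c("lambda1", "lambda2", "lambda3"))
    if (any(x <= 0)) stop("shape parameters live on the positive reals")
    A <- cmp[[paste0("A", m)]]
    B <- cmp[[paste0("B", m)]]
    vapply(x, function(xx) sum(w * dgamma(xx, shape = A, rate = B)), 0)
  } else if (param %in% c("p1", "p2")) {
    if (any(x <= 0 | x >= 1)) stop("mixing weights live on (0, 1)")
    if (param == "p1") { a <- cmp$A0; b <- cmp$B0 + cmp$C0 }
    else               { a <- cmp$B0; b <- cmp$A0 + cmp$C0 }
    vapply(x, function(xx) sum(w * dbeta(xx, a, b)), 0)
  } else {
    stop("unknown parameter: ", param)
  }
}

#' Censored mixture log-likelihood
#'
#' Evaluates the full log-likelihood of a censored-sample summary at a
#' parameter point,
#' \deqn{\ell(\Theta) = \sum_m \left[ u_m \ln p_m + u_m \ln\lambda_m -
#'   \lambda_m S_m \right] + \sum_m S_m +
#'   (n-u)\,\ln\!\big(1 - \sum_m p_m e^{-\lambda_m \ln(1/t)}\big).}
#' The data-dependent additive constant \eqn{\sum_m S_m} (from the
#' \eqn{(\lambda_m - 1)\sum \ln y} part of the density) is included, so AIC
#' and BIC computed from this value are well defined; no multiplicative
#' constants are dropped.
#'
#' @param params A [mixture_params()].
#' @param summary A [censored_summary()].
#' @return The log-likelihood (a single number).
#' @export
log_likelihood <- function(params, summary) {
  stopifnot(inherits(params, "mixture_params"),
            inherits(summary, "censored_summary"))
  u <- summary$u
  S <- summary$S
  nu <- summary$n - sum(u)
  lam <- params$lambda
  p <- params$p
  ll <- sum(u * log(p) + u * log(lam) - lam * S) + sum(S)
  if (nu > 0) {
    surv <- 1 - sum(p * exp(-lam * summary$log_inv_t))
    if (surv <= 0)
      stop("mixture survival at the censor time is not positive")
    ll <- ll + nu * log(surv)
  }
  ll
}
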