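# Independent oracles used across the test suite.  Everything here avoids
# the package's signed-expansion code path: moments come from dense tensor
# quadrature of the *unexpanded* censored likelihood times the prior.

# Gauss-Legendre nodes/weights on [a, b] via the Golub-Welsch eigenproblem.
gauss_legendre <- function(n, a = -1, b = 1) {
  k <- seq_len(n - 1)
  off <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- off
  J[cbind(k + 1, k)] <- off
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

# Generalized Gauss-Laguerre nodes/weights for weight x^alpha e^{-x} on
# (0, Inf), again via Golub-Welsch.
gauss_laguerre <- function(n, alpha = 0) {
  i <- seq_len(n)
  J <- matrix(0, n, n)
  diag(J) <- 2 * (i - 1) + alpha + 1
  off <- sqrt(i[-n] * (i[-n] + alpha))
  J[cbind(i[-n], i[-n] + 1)] <- off
  J[cbind(i[-n] + 1, i[-n])] <- off
  eg <- eigen(J, symmetric = TRUE)
  list(nodes = eg$values, weights = gamma(alpha + 1) * eg$vectors[1, ]^2)
}

# Posterior moments by 5-D tensor quadrature of L(Theta) * pi(Theta), using
# the direct likelihood form
#   prod_m lambda_m^{u_m} e^{-lambda_m S_m} p_m^{u_m}
#     * (1 - sum_m p_m e^{-lambda_m L})^{n-u}
# (no binomial expansion).  Returns E(theta^r) for each requested parameter
# and order.  Only sensible for small summaries (the tests use n - u <= 3).
# Each lambda dimension uses generalized Gauss-Laguerre with the weight
# lambda^{ex-2} e^{-rate*lambda} matched to the flattest integrand the
# orders need (r = -2), so the residual factors on the grid are low-degree
# polynomials times entire exponentials and ~20 nodes give ~1e-10 accuracy;
# the mixing-weight dimensions are (near-)polynomial, where Gauss-Legendre
# is effectively exact.
quad_posterior_moments <- function(summary, prior,
                                   orders = c(-2, -1, 1, 2),
                                   n_lambda = 20, n_p = 12) {
  u <- summary$u; S <- summary$S; L <- summary$log_inv_t
  nu <- summary$n - sum(u)
  prior <- cmpd3::prior_spec(prior)
  if (prior$family == "informative") {
    h <- unclass(prior$hyper)
    ex_l <- u + h[c("a1", "a2", "a3")] - 1   # lambda exponent in integrand
    rate <- S + h[c("b1", "b2", "b3")]
    ex_p <- u + h[c("a", "b", "c")] - 1      # p exponent in integrand
  } else {
    ex_l <- u + if (prior$family == "uniform") 0 else -1
    rate <- S
    ex_p <- u
  }
  if (any(ex_l - 2 <= -1))
    stop("toy summary too small for the Laguerre weight (need ex_l > 1)")
  gl <- lapply(1:3, function(m) {
    g <- gauss_laguerre(n_lambda, ex_l[[m]] - 2)
    # weight carries lambda^(ex_l-2) e^{-rate*lambda}; leftover factor
    # lambda^2 is applied on the grid below
    list(nodes = g$nodes / rate[[m]], weights = g$weights)
  })
  gp1 <- gauss_legendre(n_p, 1e-12, 1 - 1e-12)
  gp1 <- gauss_legendre(n_p, 1e-12, 1 - 1e-12)

  lam1 <- gl[[1]]$nodes; lam2 <- gl[[2]]$nodes; lam3 <- gl[[3]]$nodes
  # index arrays for the full tensor grid (lam1, lam2, lam3, p1, p2-nested)
  dims <- c(n_lambda, n_lambda, n_lambda, n_p, n_p)
  total <- prod(dims)
  i1 <- rep(seq_len(n_lambda), times = total / n_lambda)
  i2 <- rep(rep(seq_len(n_lambda), each = n_lambda), times = total / n_lambda^2)
  i3 <- rep(rep(seq_len(n_lambda), each = n_lambda^2),
            times = total / n_lambda^3)
  i4 <- rep(rep(seq_len(n_p), each = n_lambda^3), times = n_p)
  i5 <- rep(seq_len(n_p), each = total / n_p)

  p1 <- gp1$nodes[i4]
  # p2 runs over (0, 1 - p1): rescale the reference nodes per p1 value
  p2 <- gp1$nodes[i5] * (1 - gp1$nodes[i4])
  w_p2 <- gp1$weights[i5] * (1 - gp1$nodes[i4])
  p3 <- 1 - p1 - p2

  loglik <- 2 * (log(lam1[i1]) + log(lam2[i2]) + log(lam3[i3])) +
    ex_p[[1]] * log(p1) + ex_p[[2]] * log(p2) + ex_p[[3]] * log(p3)
  if (nu > 0) {
    surv <- 1 - p1 * exp(-lam1[i1] * L) - p2 * exp(-lam2[i2] * L) -
      p3 * exp(-lam3[i3] * L)
    surv[surv < 0] <- 0
    loglik <- loglik + nu * log(surv)
  }
  w <- gl[[1]]$weights[i1] * gl[[2]]$weights[i2] * gl[[3]]$weights[i3] *
    gp1$weights[i4] * w_p2
  dens <- exp(loglik - max(loglik)) * w
  Z <- sum(dens)
  vals <- list(lambda1 = lam1[i1], lambda2 = lam2[i2], lambda3 = lam3[i3],
               p1 = p1, p2 = p2, p3 = p3)
  out <- list()
  for (par in names(vals))
    out[[par]] <- vapply(orders, function(r) sum(dens * vals[[par]]^r) / Z,
                         0)
  for (par in names(vals)) names(out[[par]]) <- as.character(orders)
  out
}

# random small censored summaries on which all four losses are computable
# under every prior (u_m >= 3 so QLF's order -2 moments exist under JP too)
random_toy_summary <- function(max_censored = 3) {
  u <- sample(3:6, 3, replace = TRUE)
  nu <- sample(0:max_censored, 1)
  L <- runif(1, 0.2, 1.5)
  # mean ln(1/y) above L keeps the summary in the unit-scale regime
  S <- u * (L + rgamma(3, shape = 2, rate = 1.5))
  censored_summary(n = sum(u) + nu, log_inv_t = L,
                   u1 = u[1], u2 = u[2], u3 = u[3],
                   S1 = S[1], S2 = S[2], S3 = S[3])
}

# direct trinomial expansion of (1 - p1 a1 - p2 a2 - p3 a3)^nu integrated
# term by term against the prior: an independent route to Omega and to
# unnormalized moments for small nu.  Enumerates multinomial coefficients
# over (c0, c1, c2, c3) instead of the package's nested binomials.
trinomial_omega <- function(summary, prior, mom_par = NULL, mom_r = 0) {
  u <- summary$u; S <- summary$S; L <- summary$log_inv_t
  nu <- summary$n - sum(u)
  prior <- cmpd3::prior_spec(prior)
  if (prior$family == "informative") {
    h <- unclass(prior$hyper)
    sh <- u + h[c("a1", "a2", "a3")]
    rt <- S + h[c("b1", "b2", "b3")]
    dd <- h[c("a", "b", "c")]
  } else {
    sh <- u + if (prior$family == "uniform") 1 else 0
    rt <- S
    dd <- c(1, 1, 1)
  }
  total <- 0
  for (c1 in 0:nu) for (c2 in 0:(nu - c1)) for (c3 in 0:(nu - c1 - c2)) {
    c0 <- nu - c1 - c2 - c3
    coef <- exp(lfactorial(nu) - lfactorial(c0) - lfactorial(c1) -
                  lfactorial(c2) - lfactorial(c3)) * (-1)^(c1 + c2 + c3)
    A <- sh; B <- rt + c(c1, c2, c3) * L
    D <- u + dd + c(c1, c2, c3)
    term <- prod(gamma(A) / B^A) *
      exp(sum(lgamma(D)) - lgamma(sum(D)))
    if (!is.null(mom_par)) {
      if (startsWith(mom_par, "lambda")) {
        m <- as.integer(substring(mom_par, 7))
        term <- term * gamma(A[m] + mom_r) / gamma(A[m]) / B[m]^mom_r
      } else {
        s <- as.integer(substring(mom_par, 2))
        term <- term * exp(lgamma(D[s] + mom_r) - lgamma(D[s]) +
                             lgamma(sum(D)) - lgamma(sum(D) + mom_r))
      }
    }
    total <- total + coef * term
  }
  as.numeric(total)
}
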