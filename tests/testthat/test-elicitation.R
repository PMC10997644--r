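test_that("prior predictive density normalizes and is weight-symmetric", {
  h <- elicited_hyper()
  # on the negative-log scale the predictive law is a Lomax mixture whose
  # full (heavy) tail is representable; the unit-scale density is the same
  # law by the change of variables y = exp(-x)
  total <- integrate(ppd_density_neglog, 0, Inf, hyper = h,
                     rel.tol = 1e-12, subdivisions = 2000L)$value
  expect_equal(total, 1, tolerance = 1e-8)
  x <- c(0.2, 0.9, 2.5, 6)
  expect_equal(ppd_density_neglog(x, h), ppd_density(exp(-x), h) * exp(-x),
               tolerance = 1e-13)
  # equal component laws make the Dirichlet weights cancel
  h1 <- ip_hyper(0.8, 0.6, 0.8, 0.6, 0.8, 0.6, a = 2.5, b = 2.5, c = 2.0)
  h2 <- ip_hyper(0.8, 0.6, 0.8, 0.6, 0.8, 0.6, a = 9.0, b = 0.1, c = 1.3)
  y <- seq(0.05, 0.95, by = 0.1)
  expect_equal(ppd_density(y, h1), ppd_density(y, h2), tolerance = 1e-12)
  expect_error(ppd_density(c(0.5, 1.2), h), "inside \\(0, 1\\)")
})

test_that("closed-form interval probabilities match quadrature and add up", {
  h <- elicited_hyper()
  iv <- default_elicitation_intervals()
  expect_equal(nrow(iv), 9L)
  p <- ppd_interval_probability(iv$z1, iv$z2, h)
  for (i in seq_len(nrow(iv))) {
    q <- integrate(ppd_density, iv$z1[i], iv$z2[i], hyper = h,
                   rel.tol = 1e-13)$value
    expect_equal(p[i], q, tolerance = 1e-10)
  }
  # additivity of adjacent intervals
  expect_equal(ppd_interval_probability(0.05, 0.25, h), p[1] + p[2],
               tolerance = 1e-12)
  # full support carries total mass one
  expect_equal(ppd_interval_probability(0, 1, h), 1, tolerance = 1e-12)
})

test_that("density matches a Monte Carlo evaluation of the defining integral", {
  set.seed(67)
  h <- elicited_hyper()
  hv <- unclass(h)
  n <- 40000
  lam <- cbind(rgamma(n, hv["a1"], rate = hv["b1"]),
               rgamma(n, hv["a2"], rate = hv["b2"]),
               rgamma(n, hv["a3"], rate = hv["b3"]))
  g <- cbind(rgamma(n, hv["a"]), rgamma(n, hv["b"]), rgamma(n, hv["c"]))
  p <- g / rowSums(g)
  y <- 0.5
  draws <- rowSums(p * lam * y^(lam - 1))
  mc_se <- sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - ppd_density(y, h)), 3 * mc_se)
})

test_that("objective is zero at a perfect match and scales quadratically", {
  h <- elicited_hyper()
  iv <- default_elicitation_intervals()
  p <- ppd_interval_probability(iv$z1, iv$z2, h)
  perfect <- predictive_intervals(iv$z1, iv$z2, p)
  expect_equal(elicitation_objective(h, perfect), 0)
  d <- 0.2 * p
  once <- elicitation_objective(h, predictive_intervals(iv$z1, iv$z2, p - d))
  twice <- elicitation_objective(h,
                                 predictive_intervals(iv$z1, iv$z2, p - 2 * d))
  expect_equal(twice, 4 * once, tolerance = 1e-12)
  expect_gt(elicitation_objective(h, iv), 0)
})

test_that("elicitation never returns worse than its starting point", {
  iv <- default_elicitation_intervals()
  ref <- elicited_hyper()
  ref_obj <- elicitation_objective(ref, iv)
  # local polish from the reference solution cannot worsen it
  polished <- elicit_hyperparameters(iv, init = ref, n_starts = 1)
  expect_lte(attr(polished, "objective"), ref_obj)
  expect_equal(attr(polished, "objective"),
               elicitation_objective(polished, iv), tolerance = 1e-12)
})

test_that("self-consistent targets are recovered to a near-zero objective", {
  set.seed(71)
  truth <- ip_hyper(1.1, 0.9, 0.8, 0.7, 0.6, 0.5, a = 2.2, b = 2.4, c = 2.0)
  iv0 <- default_elicitation_intervals()
  targets <- ppd_interval_probability(iv0$z1, iv0$z2, truth)
  iv <- predictive_intervals(iv0$z1, iv0$z2, targets)
  fit <- elicit_hyperparameters(iv, n_starts = 6, seed = 123)
  expect_lt(attr(fit, "objective"), 1e-3^2) # relative errors below 1e-3 each
})

test_that("degenerate full-support interval is matched by any start", {
  iv <- predictive_intervals(0, 1, 1)
  init <- elicited_hyper()
  fit <- elicit_hyperparameters(iv, init = init, n_starts = 1)
  expect_equal(attr(fit, "objective"), 0)
})

test_that("elicitation is deterministic under a fixed seed", {
  iv <- default_elicitation_intervals()
  f1 <- elicit_hyperparameters(iv, n_starts = 4, seed = 99)
  f2 <- elicit_hyperparameters(iv, n_starts = 4, seed = 99)
  expect_identical(unclass(f1), unclass(f2))
})
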