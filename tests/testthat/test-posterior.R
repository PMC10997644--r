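all_priors <- c("uniform", "jeffreys", "informative")

test_that("component index set and signs follow the triple expansion", {
  post <- build_posterior(kevlar_summary(), "uniform")
  expect_equal(nrow(post$components), choose(11 + 3, 3)) # 364
  with(post$components, {
    expect_true(all(k <= j & j <= i & i <= 11))
    expect_equal(sign, (-1)^i)
  })
  # empty censoring collapses the sum to a single positive component
  s0 <- censored_summary(9, 0.5, 3, 3, 3, 4, 5, 6)
  p0 <- build_posterior(s0, "uniform")
  expect_equal(nrow(p0$components), 1L)
  expect_equal(p0$components$sign, 1)
})

test_that("normalized signed weights sum to one on random posteriors", {
  set.seed(11)
  for (rep in 1:12) {
    s <- random_toy_summary()
    pr <- all_priors[(rep - 1) %% 3 + 1]
    post <- build_posterior(s, pr)
    w <- with(post$components, sign * exp(log_abs_weight - post$log_omega))
    expect_lt(abs(sum(w) - 1), 1e-10)
    # Dirichlet mean identity survives the signed mixing
    psum <- posterior_moment(post, "p1", 1) + posterior_moment(post, "p2", 1) +
      posterior_moment(post, "p3", 1)
    expect_lt(abs(psum - 1), 1e-10)
  }
  postk <- build_posterior(kevlar_summary(), "uniform")
  wk <- with(postk$components, sign * exp(log_abs_weight - postk$log_omega))
  expect_lt(abs(sum(wk) - 1), 1e-10)
})

test_that("no-censoring posteriors collapse to analytic gamma x Dirichlet", {
  u <- c(4, 3, 5); S <- c(6.2, 4.4, 9.1)
  s0 <- censored_summary(12, 0.8, u[1], u[2], u[3], S[1], S[2], S[3])
  # uniform prior: shapes u+1, rates S, Dirichlet exponents u+1
  post <- build_posterior(s0, "uniform")
  for (m in 1:3) {
    A <- u[m] + 1; B <- S[m]
    expect_equal(posterior_moment_lambda(post, m, 1), A / B,
                 tolerance = 1e-12)
    expect_equal(posterior_moment_lambda(post, m, 2), A * (A + 1) / B^2,
                 tolerance = 1e-12)
    expect_equal(posterior_moment_lambda(post, m, -1), B / (A - 1),
                 tolerance = 1e-12)
  }
  D <- u + 1
  for (sdx in 1:3)
    expect_equal(posterior_moment_proportion(post, sdx, 1), D[sdx] / sum(D),
                 tolerance = 1e-12)
  # informative prior: shapes u + a_m, rates S + b_m, Dirichlet u + (a,b,c)
  h <- elicited_hyper()
  posti <- build_posterior(s0, prior_spec("informative", h))
  expect_equal(posterior_moment_lambda(posti, 1, 1),
               (u[1] + h[["a1"]]) / (S[1] + h[["b1"]]), tolerance = 1e-12)
  Di <- u + unclass(h)[c("a", "b", "c")]
  expect_equal(posterior_moment_proportion(posti, 2, 1), Di[[2]] / sum(Di),
               tolerance = 1e-12)
})

test_that("posterior matches the direct trinomial expansion at n - u = 2", {
  set.seed(23)
  for (pr in all_priors) {
    s <- random_toy_summary(max_censored = 0)
    s <- censored_summary(sum(s$u) + 2, s$log_inv_t, s$u[1], s$u[2], s$u[3],
                          s$S[1], s$S[2], s$S[3])
    post <- build_posterior(s, pr)
    om <- trinomial_omega(s, pr)
    expect_equal(exp(post$log_omega), om, tolerance = 1e-10)
    for (par in c("lambda1", "p2")) {
      expect_equal(posterior_moment(post, par, 1),
                   trinomial_omega(s, pr, par, 1) / om, tolerance = 1e-10)
      expect_equal(posterior_moment(post, par, 2),
                   trinomial_omega(s, pr, par, 2) / om, tolerance = 1e-10)
    }
  }
})

test_that("moments match dense quadrature of the unexpanded posterior", {
  # small spot check; the full >= 50-summary sweep runs in test-acceptance
  set.seed(31)
  for (pr in all_priors) {
    s <- random_toy_summary()
    post <- build_posterior(s, pr)
    q <- quad_posterior_moments(s, pr)
    for (par in c("lambda1", "lambda3", "p1", "p2"))
      for (r in c(-2, -1, 1, 2))
        expect_equal(posterior_moment(post, par, r),
                     unname(q[[par]][as.character(r)]),
                     tolerance = 1e-3)
  }
})

test_that("r = 0 returns exactly one", {
  post <- build_posterior(kevlar_summary(), "jeffreys")
  expect_identical(posterior_moment(post, "lambda2", 0), 1)
  expect_identical(posterior_moment(post, "p1", 0), 1)
})

test_that("marginal densities integrate to one and reproduce their moments", {
  post <- build_posterior(kevlar_summary(), "uniform")
  for (par in c("lambda1", "p1")) {
    upper <- if (startsWith(par, "lambda")) Inf else 1
    total <- integrate(function(x) marginal_pdf(post, par, x), 0, upper,
                       rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
    mean_q <- integrate(function(x) x * marginal_pdf(post, par, x), 0, upper,
                        rel.tol = 1e-9)$value
    expect_equal(mean_q, posterior_moment(post, par, 1), tolerance = 1e-6)
  }
  # collapse case: marginal is exactly a gamma density
  s0 <- censored_summary(9, 0.5, 3, 3, 3, 4, 5, 6)
  p0 <- build_posterior(s0, "uniform")
  x <- c(0.3, 0.8, 1.9)
  expect_equal(marginal_pdf(p0, "lambda1", x), dgamma(x, 4, rate = 4),
               tolerance = 1e-12)
})

test_that("validity violations raise the documented errors", {
  s <- censored_summary(10, 0.5, 0, 4, 4, 0, 5, 6)
  expect_error(build_posterior(s, "jeffreys"), "u_m >= 1")
  # u_1 = 0 with no censoring and no informative rate: improper under UP
  s0 <- censored_summary(8, 0.5, 0, 4, 4, 0, 5, 6)
  expect_error(build_posterior(s0, "uniform"), "improper")
  # but the informative prior's rate b_1 repairs it
  expect_s3_class(build_posterior(s0, "informative"), "cmpd3_posterior")
  # moment order beyond the minimum shape names the violation
  sj <- censored_summary(8, 0.5, 1, 3, 3, 2, 4, 5)
  pj <- build_posterior(sj, "jeffreys")
  expect_error(posterior_moment(pj, "lambda1", -2), "order -2")
  expect_error(posterior_moment(pj, "lambda1", -1), "order -1")
  expect_error(marginal_pdf(pj, "lambda1", -1), "positive reals")
  expect_error(marginal_pdf(pj, "p1", 1.5), "\\(0, 1\\)")
})

test_that("catastrophic cancellation is detected, not returned", {
  # heavy censoring with t near 1 makes {S(t)}^{n-u} vanish: the alternating
  # sum loses all significant digits and must fail loudly
  s <- censored_summary(80, 0.02, 4, 4, 4, 3, 3, 3)
  expect_error(build_posterior(s, "uniform"), "cancellation")
})

test_that("log-likelihood agrees with a per-observation product", {
  set.seed(47)
  params <- mixture_params(0.7, 1.2, 0.5, 0.4, 0.35)
  d <- data.frame(component = sample(1:3, 25, replace = TRUE),
                  value = runif(25, 0.01, 0.99))
  t <- 0.7
  s <- summarize_censored(d, censor_time = t, quiet = TRUE)
  obs <- d$value <= t
  direct <- sum(vapply(which(obs), function(i)
    log(params$p[d$component[i]] *
          dpower(d$value[i], params$lambda[d$component[i]])), 0)) +
    sum(!obs) * log(scmpd3(t, params))
  expect_equal(log_likelihood(params, s), direct, tolerance = 1e-10)
  # censor term vanishes as t -> 0 (log_inv_t -> Inf)
  sfar <- censored_summary(s$n, 50, s$u[1], s$u[2], s$u[3],
                           s$S[1], s$S[2], s$S[3])
  no_censor <- sum(s$u * log(params$p) + s$u * log(params$lambda) -
                     params$lambda * s$S) + sum(s$S)
  expect_equal(log_likelihood(params, sfar), no_censor, tolerance = 1e-10)
})
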