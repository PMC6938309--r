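test_that("generator matrix follows the log-linear intensity form", {
  m0 <- intensity_model()
  Q <- build_generator(m0, c(log(0.2), log(0.5)), numeric(0))
  expect_equal(unname(Q), matrix(c(-0.2, 0.5, 0.2, -0.5), 2))
  expect_equal(rowSums(Q), c(NoAUD = 0, AUD = 0))

  # one-unit covariate increase multiplies the intensity by its hazard ratio
  m <- intensity_model("cannabis")
  p <- c(log(0.2), log(0.5), log(1.18), 0)
  q_lo <- build_generator(m, p, c(cannabis = 1))[1, 2]
  q_hi <- build_generator(m, p, c(cannabis = 2))[1, 2]
  expect_equal(q_hi / q_lo, 1.18)

  # overflow guard names the configuration
  expect_error(build_generator(m, c(0, 0, 10, 0), c(cannabis = 10)),
               "exceeds \\+/-50.*cannabis")
})

test_that("closed-form transition matrix matches its derivation and limits", {
  Q <- matrix(c(-0.5, 1, 0.5, -1), 2)
  P <- transition_matrix(Q, 1)
  expect_equal(P[1, 1], (1 + 0.5 * exp(-1.5)) / 1.5, tolerance = 1e-15)
  expect_equal(P[1, 1], 0.7410434, tolerance = 1e-7)
  expect_equal(P[1, 2], 0.2589566, tolerance = 1e-7)
  expect_equal(rowSums(P), c(1, 1))
  # no-event limits
  expect_equal(transition_matrix(Q, 0), diag(2))
  expect_equal(transition_matrix(matrix(0, 2, 2), 5), diag(2))
  # stationary limit P00 -> q10/(q01+q10)
  expect_equal(transition_matrix(Q, 1e6)[1, 1], 1 / 1.5, tolerance = 1e-12)
  expect_error(transition_matrix(Q, -1), "non-negative")
})

test_that("Chapman-Kolmogorov holds for the closed form", {
  for (rates in list(c(0.01, 0.3), c(2, 0.05), c(0.7, 0.7))) {
    Q <- matrix(c(-rates[1], rates[2], rates[1], -rates[2]), 2)
    P_s <- transition_matrix(Q, 2.5)
    P_t <- transition_matrix(Q, 4)
    expect_equal(P_s %*% P_t, transition_matrix(Q, 6.5), tolerance = 1e-10)
  }
})

test_that("cohort log-likelihood is additive and order-invariant", {
  pairs <- make_pairs(pre = c(0, 0, 1), post = c(1, 0, 0), dt = c(1, 6, 3))
  m0 <- intensity_model()
  p <- c(log(0.5), log(1))
  ll <- cohort_loglik(m0, p, pairs)
  # single-pair value from the closed form
  one <- make_pairs(pre = 0, post = 1, dt = 1)
  expect_equal(cohort_loglik(m0, p, one), log(0.2589566), tolerance = 1e-6)
  # duplicating every pair doubles the log-likelihood
  expect_equal(cohort_loglik(m0, p, rbind(pairs, pairs)), 2 * ll)
  # permutation leaves the value bit-identical (stable summation)
  expect_identical(cohort_loglik(m0, p, pairs[c(3, 1, 2), ]), ll)
})

test_that("analytic score matches central finite differences", {
  set.seed(42)
  pairs <- make_pairs(pre = rbinom(150, 1, 0.3), post = rbinom(150, 1, 0.4),
                      dt = runif(150, 3, 9),
                      x = rnorm(150), y = rnorm(150))
  m <- intensity_model(c("x", "y"), constrained = "y")
  p0 <- c(-3.5, -1.8, 0.25, -0.15, 0.2)
  d <- audmc:::pair_design(m, pairs)
  g <- audmc:::score_from_design(m, p0, d)
  fd <- vapply(seq_along(p0), function(i) {
    h <- 1e-6; e <- replace(numeric(5), i, h)
    (audmc:::loglik_from_design(m, p0 + e, d) -
       audmc:::loglik_from_design(m, p0 - e, d)) / (2 * h)
  }, numeric(1))
  expect_equal(g, fd, tolerance = 1e-6)
})

test_that("intercept-only MLE on symmetric pair counts matches a brute-force grid", {
  # same stay/switch split out of both states at a common gap: the
  # likelihood is symmetric in (q01, q10), so the fitted rates coincide
  pairs <- make_pairs(pre = rep(c(0, 1), each = 8),
                      post = c(rep(0, 6), 1, 1, rep(1, 6), 0, 0),
                      dt = 6)
  fit <- fit_mle(intensity_model(), pairs, starts = 1)
  expect_true(fit$convergence)
  q_hat <- exp(fit$estimate)
  expect_equal(unname(q_hat[1]), unname(q_hat[2]), tolerance = 1e-6)
  # brute-force grid oracle over (q01, q10)
  grid <- expand.grid(q01 = exp(seq(-6, 0, length.out = 150)),
                      q10 = exp(seq(-6, 0, length.out = 150)))
  ll <- mapply(function(a, b)
    cohort_loglik(intensity_model(), c(log(a), log(b)), pairs),
    grid$q01, grid$q10)
  best <- grid[which.max(ll), ]
  expect_equal(unname(q_hat[1]), best$q01, tolerance = 0.05)
  expect_equal(unname(q_hat[2]), best$q10, tolerance = 0.05)
  expect_gte(fit$loglik, max(ll) - 1e-8)
})

test_that("constant covariates are flagged as unidentifiable", {
  pairs <- balanced_pairs(k = 3)
  pairs$flat <- 1
  expect_warning(
    fit <- fit_mle(intensity_model("flat"), pairs, starts = 1,
                   hessian = FALSE),
    "constant across pairs")
  expect_equal(fit$degenerate_covariates, "flat")
})

test_that("constrained models never beat their unconstrained parent", {
  set.seed(7)
  spec <- cohort_spec("state_dependent", n_subjects = 120, seed = 11,
                      covariate_processes = default_covariate_processes()["cannabis"])
  pairs <- build_transition_pairs(generate_cohort(spec))
  fu <- fit_mle(intensity_model("cannabis"), pairs, starts = 1)
  fc <- fit_mle(intensity_model("cannabis", constrained = "cannabis"),
                pairs, starts = 1)
  expect_lte(fc$loglik, fu$loglik + 1e-8)
})

test_that("hazard ratios exponentiate coefficients with Wald intervals", {
  pairs <- balanced_pairs(k = 10)
  set.seed(1)
  pairs$x <- rnorm(nrow(pairs))
  fit <- fit_mle(intensity_model("x"), pairs, starts = 1)
  hr <- hazard_ratios(fit)
  expect_true(all(hr$hr > 0))
  b <- fit$estimate["onset_x"]
  se <- sqrt(fit$vcov["onset_x", "onset_x"])
  row <- hr[hr$covariate == "x" & hr$transition == "onset", ]
  expect_equal(row$hr, unname(exp(b)))
  expect_equal(row$lower, unname(exp(b - qnorm(0.975) * se)))
})

test_that("standardization toggle returns per-unit estimates", {
  set.seed(5)
  spec <- cohort_spec(model = intensity_model("cannabis"),
                      params = c(-5, -2.5, 0.25, -0.1),
                      covariate_processes = default_covariate_processes()["cannabis"],
                      n_subjects = 400)
  pairs <- build_transition_pairs(generate_cohort(spec, seed = 2))
  f_raw <- fit_mle(spec$model, pairs, starts = 1)
  f_std <- fit_mle(spec$model, pairs, starts = 1, standardize = TRUE)
  expect_equal(f_std$estimate, f_raw$estimate, tolerance = 1e-3)
  expect_equal(sqrt(diag(f_std$vcov)), sqrt(diag(f_raw$vcov)),
               tolerance = 1e-2)
})
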