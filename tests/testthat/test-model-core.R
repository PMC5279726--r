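test_that("self-feedback likelihood matches its closed Gaussian form", {
  p0 <- model_params(sigma_m = 1, sigma_f = 0)
  expect_equal(feedback_likelihood_self(0, 0, p0), 1 / sqrt(2 * pi))

  # one combined-SD away from the motor plan
  p <- finch_params()
  s <- sqrt(23^2 + 46^2)
  expect_equal(feedback_likelihood_self(s, 0, p),
               exp(-0.5) / sqrt(2 * pi * (23^2 + 46^2)))

  # density and log-density are consistent far into the tails
  ld <- feedback_likelihood_self(c(0, 100, 500, 2000), 0, p, log = TRUE)
  expect_true(all(is.finite(ld)))
  expect_equal(exp(ld[1:2]), feedback_likelihood_self(c(0, 100), 0, p))
})

test_that("likelihood closed form agrees with quadrature of its defining integral", {
  # marginal over the unknown produced pitch: independent oracle
  p <- finch_params()
  oracle <- integrate(function(q) {
    dnorm(100, q, p$sigma_f) * dnorm(q, 0, p$sigma_m)
  }, -8 * p$sigma_m, 8 * p$sigma_m, rel.tol = 1e-12)$value
  got <- feedback_likelihood_self(100, 0, p)
  expect_equal(got, oracle, tolerance = 1e-8)
})

test_that("likelihood rejects non-finite inputs and is 0 in the deaf limit", {
  p <- finch_params()
  expect_error(feedback_likelihood_self(Inf, 0, p), class = "pitchadapt_domain_error")
  expect_error(feedback_likelihood_self(0, NA, p), class = "pitchadapt_domain_error")
  deaf <- model_params(sigma_m = 46, sigma_f = Inf, k = 1.5e-4)
  expect_identical(feedback_likelihood_self(c(-50, 0, 50), 0, deaf), c(0, 0, 0))
  expect_identical(feedback_likelihood_self(0, 0, deaf, log = TRUE), -Inf)
})

test_that("self posterior follows L / (L + k) and its limiting cases", {
  p <- finch_params()
  # k chosen equal to the likelihood at a point gives exactly 1/2
  L <- feedback_likelihood_self(40, 0, p)
  p_half <- model_params(sigma_m = 46, sigma_f = 23, k = L)
  expect_equal(self_posterior(40, 0, p_half), 0.5)

  # direct evaluation at the motor plan, cross-checked against log path
  L0 <- 1 / sqrt(2 * pi * (23^2 + 46^2))
  expect_equal(self_posterior(0, 0, p), L0 / (L0 + 1.5e-4), tolerance = 1e-12)

  # clamped and k = 0 paths are both exactly 1 where L > 0
  clamped <- model_params(sigma_m = 46, sigma_f = 23, clamp_self = TRUE)
  k0 <- model_params(sigma_m = 46, sigma_f = 23, k = 0)
  expect_identical(self_posterior(c(-500, 0, 500), 0, clamped), c(1, 1, 1))
  expect_identical(self_posterior(c(-500, 0, 500), 0, k0), c(1, 1, 1))

  # k = 0 with zero likelihood is 0/0 and must error
  deaf_k0 <- model_params(sigma_m = 46, sigma_f = Inf, k = 0)
  expect_error(self_posterior(0, 0, deaf_k0),
               class = "pitchadapt_degenerate_posterior")
})

test_that("self posterior is bounded and non-increasing in |p_f - mu_m|", {
  p <- finch_params()
  dist <- seq(0, 600, by = 5)
  post <- self_posterior(dist, 0, p)
  expect_true(all(post > 0 & post <= 1))
  expect_true(all(diff(post) <= 0))
  # symmetric around the motor plan, and survives extreme shifts by log-space
  expect_equal(self_posterior(-dist, 0, p), post)
  expect_gt(self_posterior(1000, 0, p), 0)
})

test_that("combined pitch is the precision-weighted average with correct limits", {
  perfect <- model_params(sigma_m = 46, sigma_f = 0)
  expect_equal(combined_pitch(120, 30, perfect), 120)
  equal <- model_params(sigma_m = 20, sigma_f = 20)
  expect_equal(combined_pitch(120, 30, equal), 75)
  deaf <- model_params(sigma_m = 46, sigma_f = Inf)
  expect_equal(combined_pitch(120, 30, deaf), 30)
  # always between prior and feedback
  p <- finch_params()
  po <- combined_pitch(c(-200, -5, 80, 300), 10, p)
  expect_true(all(po >= pmin(c(-200, -5, 80, 300), 10) &
                  po <= pmax(c(-200, -5, 80, 300), 10)))
})

test_that("perceived deviation: closed form, mixture form and limits agree", {
  p <- finch_params()
  # on-target feedback with no bias perceives no deviation
  expect_equal(perceived_deviation(p$mu_target, 0, p), 0)

  # perfect sensor under the clamp: full error transfer
  clamp0 <- model_params(mu_target = 500, sigma_m = 46, sigma_f = 0,
                         clamp_self = TRUE)
  expect_equal(perceived_deviation(620, 7, clamp0), 620 - 500)

  # mixture form P(s) p_opt + P(e) mu_m - mu* equals the closed form
  withr::with_seed(11, {
    for (i in 1:25) {
      pr <- model_params(mu_target = runif(1, -200, 200),
                         sigma_m = runif(1, 5, 60), sigma_f = runif(1, 0, 40),
                         k = 10^runif(1, -8, -2))
      eps <- runif(1, -80, 80)
      p_f <- runif(1, -400, 400)
      mu_m <- pr$mu_target + eps
      post <- self_posterior(p_f, mu_m, pr)
      mixture <- post * combined_pitch(p_f, mu_m, pr) +
        (1 - post) * mu_m - pr$mu_target
      expect_equal(perceived_deviation(p_f, eps, pr), mixture, tolerance = 1e-10)
    }
  })
})

test_that("model is invariant under translating the pitch target", {
  shift_by <- 3170
  a <- model_params(mu_target = 0, sigma_m = 46, sigma_f = 23, k = 1.5e-4)
  b <- model_params(mu_target = shift_by, sigma_m = 46, sigma_f = 23, k = 1.5e-4)
  p_f <- c(-150, 20, 90, 260)
  expect_equal(self_posterior(p_f + shift_by, shift_by, b),
               self_posterior(p_f, 0, a))
  expect_equal(perceived_deviation(p_f + shift_by, -12, b),
               perceived_deviation(p_f, -12, a))
  expect_equal(solve_equilibrium_deterministic(100, b)$epsilon,
               solve_equilibrium_deterministic(100, a)$epsilon)
})

test_that("sampled renditions respect the generative model", {
  p <- finch_params()
  r1 <- withr::with_seed(5, sample_renditions(1000, epsilon = -10, p_shift = 50, p))
  r2 <- withr::with_seed(5, sample_renditions(1000, epsilon = -10, p_shift = 50, p))
  expect_identical(r1, r2)                      # determinism under seeding
  expect_identical(r1$p_ear, r1$p + 50)         # impinging pitch identity
  expect_true(all(r1$post_self >= 0 & r1$post_self <= 1))

  # near-deterministic motor: produced pitch pinned at mu* + eps
  tight <- model_params(sigma_m = 1e-9, sigma_f = 23, k = 1.5e-4)
  rt <- withr::with_seed(1, sample_renditions(10, epsilon = 4, p_shift = 0, tight))
  expect_equal(rt$p, rep(4, 10), tolerance = 1e-6)

  # law of large numbers: mean feedback near mu* + shift at epsilon = 0
  big <- withr::with_seed(7, sample_renditions(1e5, epsilon = 0, p_shift = 50, p))
  se <- sqrt(23^2 + 46^2) / sqrt(1e5)
  expect_lt(abs(mean(big$p_f) - 50), 3 * se)
})
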