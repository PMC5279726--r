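test_that("deterministic solver reproduces the pinned-posterior closed form", {
  triples <- random_triples(8, seed = 21)
  for (i in seq_len(nrow(triples))) {
    tr <- triples[i, ]
    clamped <- model_params(sigma_m = tr$sigma_m, sigma_f = tr$sigma_f,
                            clamp_self = TRUE)
    got <- solve_equilibrium_deterministic(tr$p_shift, clamped)$epsilon
    expect_equal(got, closed_form_eps(tr$p_shift, tr$sigma_m, tr$sigma_f),
                 tolerance = 1e-9)
  }
  # k = 0 takes a distinct code path but must give the same fixed point
  k0 <- model_params(sigma_m = 32, sigma_f = 7.5, k = 0)
  expect_equal(solve_equilibrium_deterministic(100, k0)$epsilon,
               closed_form_eps(100, 32, 7.5), tolerance = 1e-9)
})

test_that("equilibrium bias is odd in the shift and zero without one", {
  p <- finch_params()
  expect_equal(solve_equilibrium_deterministic(0, p)$epsilon, 0)
  for (pd in c(25, 80, 180)) {
    expect_equal(solve_equilibrium_deterministic(-pd, p)$epsilon,
                 -solve_equilibrium_deterministic(pd, p)$epsilon,
                 tolerance = 1e-10)
  }
  # percent compensation is undefined at zero shift, never 0/0
  expect_true(is.na(solve_equilibrium_deterministic(0, p)$percent_compensation))
})

test_that("deaf limit gives exactly zero adaptation", {
  deaf <- model_params(sigma_m = 46, sigma_f = Inf, k = 1.5e-4)
  expect_identical(solve_equilibrium_deterministic(100, deaf)$epsilon, 0)
  st <- solve_equilibrium_stochastic(100, deaf, seed = 3)
  expect_identical(st$epsilon, 0)
  # irreconcilably large shifts: posterior vanishes, adaptation dies off
  p <- finch_params()
  expect_lt(abs(solve_equilibrium_deterministic(1e4, p)$epsilon), 1e-8)
})

test_that("stochastic iteration converges to the no-shift and clamped fixed points", {
  p <- finch_params()
  null <- solve_equilibrium_stochastic(0, p, seed = 2)
  expect_true(null$converged)
  expect_lt(abs(null$epsilon), 3 * max(null$se, 1e-3))

  clamped <- model_params(sigma_m = 32, sigma_f = 7.5, clamp_self = TRUE)
  st <- solve_equilibrium_stochastic(100, clamped, seed = 4)
  expect_true(st$converged)
  expect_lt(abs(st$epsilon - closed_form_eps(100, 32, 7.5)), 3 * st$se)
})

test_that("stochastic and deterministic solvers agree within Monte-Carlo error", {
  triples <- random_triples(5, seed = 33)
  for (i in seq_len(nrow(triples))) {
    tr <- triples[i, ]
    p <- model_params(sigma_m = tr$sigma_m, sigma_f = tr$sigma_f, k = 1.5e-4)
    det <- solve_equilibrium_deterministic(tr$p_shift, p)$epsilon
    st <- solve_equilibrium_stochastic(tr$p_shift, p, seed = 100 + i)
    expect_lt(abs(st$epsilon - det), 3 * st$se)
  }
})

test_that("non-convergence is flagged, never silent", {
  clamped <- model_params(sigma_m = 46, sigma_f = 0, clamp_self = TRUE)
  st <- solve_equilibrium_stochastic(100, clamped, seed = 1, max_batches = 100)
  expect_false(st$converged)
  expect_identical(st$n_batches, 100L)
})

test_that("trailing-window variability settles as the iteration equilibrates", {
  p <- finch_params()
  # tol = 0 disables early stopping so the full trajectory is observed
  st <- solve_equilibrium_stochastic(100, p, seed = 9, tol = 0,
                                     max_batches = 3000)
  expect_false(st$converged)
  early <- var(st$trajectory[101:300])
  late <- var(st$trajectory[2801:3000])
  expect_lt(late, early)
})

test_that("reported epsilon is the trailing-window mean of the trajectory", {
  p <- finch_params()
  st <- solve_equilibrium_stochastic(60, p, seed = 12, window = 40)
  w <- 40
  expect_equal(st$epsilon,
               mean(st$trajectory[(st$n_batches - w + 1):st$n_batches]))
})

test_that("learning time constant scales with the external-posterior odds", {
  clamped <- model_params(sigma_m = 46, sigma_f = 23, clamp_self = TRUE)
  expect_identical(learning_time_constant(100, clamped, epsilon = -40, q = 3), 0)
  p <- finch_params()
  expect_identical(learning_time_constant(100, p, epsilon = -40, q = 0), 0)
  t1 <- learning_time_constant(100, p, epsilon = -40, q = 1, seed = 6)
  p2 <- model_params(sigma_m = 46, sigma_f = 23, k = 3e-4)
  t2 <- learning_time_constant(100, p2, epsilon = -40, q = 1, seed = 6)
  expect_gt(t1, 0)
  expect_gt(t2, t1)   # doubling k doubles the prior odds of "external"
})

test_that("equilibrium results tidy and glance cleanly", {
  p <- finch_params()
  st <- solve_equilibrium_stochastic(100, p, seed = 8)
  td <- tidy(st)
  expect_identical(td$term, c("epsilon", "percent_compensation"))
  expect_equal(td$estimate[1], st$epsilon)
  gl <- glance(st)
  expect_identical(gl$method, "stochastic")
  expect_identical(gl$converged, st$converged)
  expect_s3_class(autoplot(st), "ggplot")
})
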