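## Equilibrium corrective bias: the epsilon at which the average
## perceived deviation across renditions vanishes, <delta_p> = 0.
##
## Key structural fact exploited by the deterministic solver: with
## mu_m = mu_target + epsilon, the feedback residual u = p_f - mu_m is
## distributed N(p_shift, sigma_m^2 + sigma_f^2) *independently of
## epsilon* (the motor plan cancels).  Hence
##   E[delta_p] = epsilon + w * E[u P(s|u)],   w = sigma_m^2 / (sigma_f^2 + sigma_m^2)
## is exactly linear in epsilon with unit slope, and its root is the
## single quadrature  epsilon* = -w * E[u P(s|u)].

## Gauss-Hermite rule cached per node count (nodes are deterministic)
gh_cache <- new.env(parent = emptyenv())
gh_rule <- function(n_nodes) {
  key <- as.character(n_nodes)
  if (is.null(gh_cache[[key]])) gh_cache[[key]] <- pracma::gaussHermite(n_nodes)
  gh_cache[[key]]
}

## E[u * P(s|u)] for u ~ N(p_shift, s2), s2 = sigma_m^2 + sigma_f^2.
## Gauss-Hermite is effectively exact here: the integrand is the
## Gaussian weight times a smooth logistic-of-quadratic factor.
expected_weighted_residual <- function(p_shift, params, n_nodes = 80) {
  s <- combined_sd(params)
  gh <- gh_rule(n_nodes)
  u <- p_shift + sqrt(2) * s * gh$x
  post <- if (self_locked(params)) 1
          else plogis(dnorm(u, 0, s, log = TRUE) - log(params$k))
  sum(gh$w * u * post) / sqrt(pi)
}

percent_comp <- function(epsilon, p_shift, epsilon0 = 0) {
  ifelse(p_shift == 0, NA_real_, 100 * abs(epsilon + epsilon0) / abs(p_shift))
}

new_equilibrium <- function(epsilon, p_shift, params, method, trajectory = NULL,
                            n_per_batch = NA_integer_, eta = NA_real_,
                            seed = NA_integer_, n_batches = NA_integer_,
                            converged = TRUE, se = 0, drift = 0) {
  structure(
    list(epsilon = epsilon,
         percent_compensation = percent_comp(epsilon, p_shift, params$epsilon0),
         p_shift = p_shift, params = params, method = method,
         trajectory = trajectory, n_per_batch = n_per_batch, eta = eta,
         seed = seed, n_batches = n_batches, converged = converged,
         se = se, drift = drift),
    class = "pitch_equilibrium")
}

#' Deterministic equilibrium corrective bias
#'
#' Finds the corrective bias \eqn{\epsilon} at which the expected
#' perceived deviation vanishes, replacing the sampled batch average of
#' the stochastic iteration by an exact expectation over the feedback
#' marginal.  Because the feedback residual distribution does not depend
#' on \eqn{\epsilon}, the expectation is linear in \eqn{\epsilon} with
#' unit slope and the root is obtained from a single Gauss--Hermite
#' quadrature.  Serves as the fast, noise-free oracle for
#' [solve_equilibrium_stochastic()] and as the default engine for curve
#' prediction and fitting.
#'
#' In the deaf limit (`sigma_f = Inf`) the feedback term is exactly zero
#' and the equilibrium bias is 0 for any shift.  With `clamp_self` (or
#' `k = 0`) the posterior is 1 and the solution is the closed form
#' \eqn{\epsilon = -p_\Delta\, \sigma_m^2 / (\sigma_m^2 + \sigma_f^2)}.
#'
#' @param p_shift Feedback shift \eqn{p_\Delta} in cents (finite scalar).
#' @param params A [model_params()] object.
#' @param n_nodes Number of Gauss--Hermite quadrature nodes.
#' @return A `pitch_equilibrium` object; see [tidy.pitch_equilibrium()].
#' @examples
#' params <- model_params(sigma_m = 46, sigma_f = 23, k = 1.5e-4)
#' solve_equilibrium_deterministic(100, params)
#' @export
solve_equilibrium_deterministic <- function(p_shift, params, n_nodes = 80) {
  validate_model_params(params)
  stopifnot(is.numeric(p_shift), length(p_shift) == 1L, is.finite(p_shift))
  if (is_deaf(params)) {
    return(new_equilibrium(0, p_shift, params, "deterministic"))
  }
  w <- feedback_weight(params)
  eps <- -w * expected_weighted_residual(p_shift, params, n_nodes)
  ## sanity: the root of the (linear, unit-slope) expected deviation
  ## must lie in the a-priori bracket
  lim <- abs(p_shift) + 4 * params$sigma_m
  if (abs(eps) > lim) {
    abort(sprintf("equilibrium %.3g outside expected bracket [%.3g, %.3g]",
                  eps, -lim, lim),
          class = "pitchadapt_numerical_error")
  }
  new_equilibrium(eps, p_shift, params, "deterministic")
}

#' Stochastic equilibrium corrective bias
#'
#' The sampling-based fixed-point iteration for the corrective bias:
#' starting from \eqn{\epsilon = 0}, repeatedly draw a batch of `n_per_batch`
#' renditions at the current bias, compute their perceived deviations,
#' and update \eqn{\epsilon \leftarrow \epsilon - \eta \langle \Delta p \rangle_n}
#' until the trailing-window mean of \eqn{\epsilon} stabilizes.
#'
#' Convergence is declared when the mean of the last `window` batch
#' values of \eqn{\epsilon} differs from the mean of the preceding
#' `window` by less than `tol` cents; the reported `epsilon` is the
#' trailing-window mean.  Exceeding `max_batches` yields a result
#' flagged `converged = FALSE`, never a silent answer.
#'
#' The result's `se` is a Monte-Carlo standard error that combines the
#' autocorrelation-corrected sampling noise of the trailing window with
#' a geometric extrapolation of the residual approach drift (the
#' iteration relaxes towards the fixed point with rate \eqn{\eta} per
#' batch, so the difference between consecutive window means estimates
#' the bias still to decay).  Agreement with the deterministic solver
#' within ~3 `se` is the expected behaviour and is property-tested.
#'
#' @inheritParams solve_equilibrium_deterministic
#' @param n_per_batch Renditions per batch (the algorithm's `n`).
#' @param eta Learning rate per batch.
#' @param seed Integer seed; the run is fully reproducible.
#' @param window Trailing-window length in batches.
#' @param tol Convergence tolerance on the window-mean change, cents.
#' @param max_batches Iteration budget.
#' @return A `pitch_equilibrium` object with the batch trajectory.
#' @examples
#' params <- model_params(sigma_m = 46, sigma_f = 23, k = 1.5e-4)
#' solve_equilibrium_stochastic(100, params, seed = 1)
#' @export
solve_equilibrium_stochastic <- function(p_shift, params, n_per_batch = 200,
                                         eta = 0.001, seed = 1, window = 50,
                                         tol = 0.05, max_batches = 5000) {
  validate_model_params(params)
  stopifnot(is.numeric(p_shift), length(p_shift) == 1L, is.finite(p_shift),
            n_per_batch >= 1, eta > 0, window >= 2,
            max_batches >= 2 * window)
  n_per_batch <- as.integer(n_per_batch)
  max_batches <- as.integer(max_batches)
  window <- as.integer(window)
  deaf <- is_deaf(params)
  if (deaf && self_locked(params) && !params$clamp_self) {
    abort("solve_equilibrium_stochastic: k = 0 in the deaf limit is degenerate",
          class = "pitchadapt_degenerate_posterior")
  }
  w <- feedback_weight(params)
  s <- combined_sd(params)
  log_k <- if (self_locked(params)) NA_real_ else log(params$k)
  traj <- numeric(max_batches)
  eps <- 0
  converged <- FALSE
  n_batches <- max_batches
  withr::with_seed(seed, {
    for (b in seq_len(max_batches)) {
      ## u = p_f - mu_m ~ N(p_shift, s^2); the motor plan cancels
      if (deaf) {
        mean_dp <- eps                       # feedback term is exactly 0
      } else {
        u <- rnorm(n_per_batch, p_shift, s)
        post <- if (self_locked(params)) 1
                else plogis(dnorm(u, 0, s, log = TRUE) - log_k)
        mean_dp <- eps + w * mean(u * post)
      }
      eps <- eps - eta * mean_dp
      traj[b] <- eps
      if (b >= 2 * window) {
        m1 <- mean(traj[(b - window + 1):b])
        m2 <- mean(traj[(b - 2 * window + 1):(b - window)])
        if (abs(m1 - m2) < tol) {
          converged <- TRUE
          n_batches <- b
          break
        }
      }
    }
  })
  traj <- traj[seq_len(n_batches)]
  last <- traj[(n_batches - window + 1):n_batches]
  prev <- traj[(n_batches - 2 * window + 1):(n_batches - window)]
  m1 <- mean(last)
  m2 <- mean(prev)
  ## window means of a geometric approach: m_prev - eps* = C e^{eta W},
  ## m_last - eps* = C, so the residual drift of m_last is D / expm1(eta W)
  drift <- (m2 - m1) / expm1(eta * window)
  rho <- suppressWarnings(cor(last[-1], last[-window]))
  if (!is.finite(rho)) rho <- 0
  rho <- min(max(rho, -0.99), 0.99)
  n_eff <- max(1, window * (1 - rho) / (1 + rho))
  se_stat <- sd(last) / sqrt(n_eff)
  if (!is.finite(se_stat)) se_stat <- 0
  new_equilibrium(m1, p_shift, params, "stochastic", trajectory = traj,
                  n_per_batch = n_per_batch, eta = eta, seed = as.integer(seed),
                  n_batches = n_batches, converged = converged,
                  se = sqrt(se_stat^2 + drift^2), drift = drift)
}

#' Learning time constant from posterior evidence
#'
#' Adaptation in the model is driven only by renditions attributed to
#' the self, so the characteristic learning time scales with the odds of
#' the external attribution:
#' \eqn{\tau = q \langle P(e \mid p_f)\rangle / \langle P(s \mid p_f)\rangle},
#' with the averages taken over sampled renditions at the given bias and
#' shift and `q` an arbitrary time scale.  Under `clamp_self` the
#' external posterior is identically 0 and \eqn{\tau = 0}; if the mean
#' self posterior underflows to 0 the result is `Inf`.
#'
#' @inheritParams solve_equilibrium_deterministic
#' @param epsilon Corrective bias at which to evaluate, cents.
#' @param q Time scale multiplying the posterior odds.
#' @param n Number of sampled renditions for the averages.
#' @param seed Integer seed.
#' @return Time constant in units of `q`.
#' @export
learning_time_constant <- function(p_shift, params, epsilon, q = 1,
                                   n = 10000, seed = 1) {
  validate_model_params(params)
  stopifnot(is.numeric(q), length(q) == 1L, is.finite(q), n >= 1)
  if (q == 0) return(0)
  r <- withr::with_seed(seed, sample_renditions(n, epsilon, p_shift, params))
  mean_s <- mean(r$post_self)
  mean_e <- mean(1 - r$post_self)
  if (mean_s == 0) return(Inf)
  q * mean_e / mean_s
}

#' @export
print.pitch_equilibrium <- function(x, ...) {
  cat("<pitch_equilibrium>\n")
  cat(sprintf("  method : %s\n", x$method))
  cat(sprintf("  p_shift: %g cents\n", x$p_shift))
  cat(sprintf("  epsilon: %.4f cents", x$epsilon))
  if (x$method == "stochastic") cat(sprintf("  (se %.3f)", x$se))
  cat("\n")
  pc <- x$percent_compensation
  cat(sprintf("  percent compensation: %s\n",
              if (is.na(pc)) "NA (p_shift = 0)" else sprintf("%.2f%%", pc)))
  if (x$method == "stochastic") {
    cat(sprintf("  batches: %d (n = %d, eta = %g, seed = %d, converged: %s)\n",
                x$n_batches, x$n_per_batch, x$eta, x$seed, x$converged))
  }
  invisible(x)
}

#' Tidy an equilibrium result
#'
#' @param x A `pitch_equilibrium` object.
#' @param ... Unused.
#' @return One-row tibble with the estimate and its diagnostics.
#' @export
tidy.pitch_equilibrium <- function(x, ...) {
  tibble(term = c("epsilon", "percent_compensation"),
         estimate = c(x$epsilon, x$percent_compensation),
         std.error = c(if (x$method == "stochastic") x$se else 0, NA_real_))
}

#' One-row summary of an equilibrium result
#'
#' @param x A `pitch_equilibrium` object.
#' @param ... Unused.
#' @export
glance.pitch_equilibrium <- function(x, ...) {
  tibble(p_shift = x$p_shift, epsilon = x$epsilon,
         percent_compensation = x$percent_compensation,
         method = x$method, n_batches = x$n_batches,
         n_per_batch = x$n_per_batch, eta = x$eta, seed = x$seed,
         converged = x$converged, se = x$se)
}
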