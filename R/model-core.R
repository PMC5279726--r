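#' Likelihood of auditory feedback given a self-caused source
#'
#' Marginal density of the encoded feedback `p_f` under the hypothesis
#' that it stems from the vocalizer's own production.  Motor and sensory
#' noise are independent Gaussians, so marginalizing over the (unknown)
#' produced pitch gives a Gaussian centred on the motor plan `mu_m` with
#' variance \eqn{\sigma_f^2 + \sigma_m^2}.  Computed in log space; the
#' density underflows to 0 smoothly for very deviant feedback rather
#' than being special-cased.  In the deaf limit (`sigma_f = Inf`) the
#' density is 0 for every finite `p_f`.
#'
#' @param p_f Encoded feedback pitch in cents (vectorized, finite).
#' @param mu_m Motor plan in cents (finite scalar or vector).
#' @param params A [model_params()] object.
#' @param log Return the log-density?
#' @return Density per cent (or log-density), same length as `p_f`.
#' @examples
#' params <- model_params(sigma_m = 46, sigma_f = 23)
#' feedback_likelihood_self(0, 0, params)
#' @export
feedback_likelihood_self <- function(p_f, mu_m, params, log = FALSE) {
  validate_model_params(params)
  if (!is.numeric(p_f) || any(!is.finite(p_f))) {
    abort("feedback_likelihood_self: `p_f` must be finite numeric",
          class = "pitchadapt_domain_error")
  }
  if (!is.numeric(mu_m) || any(!is.finite(mu_m))) {
    abort("feedback_likelihood_self: `mu_m` must be finite numeric",
          class = "pitchadapt_domain_error")
  }
  if (is_deaf(params)) {
    out <- rep(if (log) -Inf else 0, length.out = max(length(p_f), length(mu_m)))
    return(out)
  }
  dnorm(p_f, mean = mu_m, sd = combined_sd(params), log = log)
}

#' Posterior probability that feedback is self-caused
#'
#' Bayes' rule with a Gaussian self-source likelihood and a flat
#' external-source alternative folded into the constant `k`:
#' \eqn{P(s \mid p_f) = L / (L + k)} where `L` is
#' [feedback_likelihood_self()].  Evaluated as
#' \eqn{1 / (1 + e^{\log k - \log L})} so it stays accurate when `L`
#' underflows at shifts of hundreds of cents.  With `clamp_self` (or
#' `k = 0` and a positive likelihood) the posterior is exactly 1.
#'
#' @inheritParams feedback_likelihood_self
#' @return Posterior probability in `[0, 1]`, same length as `p_f`.
#' @examples
#' params <- model_params(sigma_m = 46, sigma_f = 23, k = 1.5e-4)
#' self_posterior(c(0, 100, 300), 0, params)
#' @export
self_posterior <- function(p_f, mu_m, params) {
  validate_model_params(params)
  if (params$clamp_self) {
    if (!is.numeric(p_f) || any(!is.finite(p_f))) {
      abort("self_posterior: `p_f` must be finite numeric",
            class = "pitchadapt_domain_error")
    }
    return(rep(1, length.out = max(length(p_f), length(mu_m))))
  }
  log_l <- feedback_likelihood_self(p_f, mu_m, params, log = TRUE)
  if (params$k == 0) {
    if (any(is.infinite(log_l))) {
      abort(paste("self_posterior: k = 0 with zero likelihood is 0/0;",
                  "use clamp_self = TRUE for the numerically safe path"),
            class = "pitchadapt_degenerate_posterior")
    }
    return(rep(1, length.out = length(log_l)))
  }
  plogis(log_l - log(params$k))
}

#' Optimally combined pitch estimate
#'
#' Precision-weighted combination of the motor plan `mu_m` (prior, with
#' motor variance) and the feedback `p_f` (likelihood, with sensory
#' variance) -- one update step of a Kalman filter:
#' \deqn{p_{opt} = \frac{\sigma_f^2 \mu_m + \sigma_m^2 p_f}{\sigma_f^2 + \sigma_m^2}.}
#' Always lies between `mu_m` and `p_f`; equals `p_f` for a perfect
#' sensor (`sigma_f = 0`) and `mu_m` in the deaf limit.
#'
#' @inheritParams feedback_likelihood_self
#' @return Combined pitch in cents.
#' @export
combined_pitch <- function(p_f, mu_m, params) {
  validate_model_params(params)
  if (is_deaf(params)) {
    return(rep(mu_m, length.out = max(length(p_f), length(mu_m))))
  }
  w <- feedback_weight(params)
  (1 - w) * mu_m + w * p_f
}

#' Perceived pitch deviation of one rendition
#'
#' The posterior-weighted pitch error the adaptive system acts on.  The
#' combined estimate is trusted only to the extent the feedback is
#' believed self-caused; external-attributed feedback leaves only the
#' motor plan, so the deviation collapses to the current corrective bias:
#' \deqn{\Delta p = P(s \mid p_f)\, p_{opt} + P(e \mid p_f)\, \mu_m - \mu^*
#'   = \epsilon + (p_f - \mu_m)\, P(s \mid p_f)\,
#'     \frac{\sigma_m^2}{\sigma_f^2 + \sigma_m^2},}
#' with motor plan \eqn{\mu_m = \mu^* + \epsilon}.  The closed form on
#' the right is what is computed; it is algebraically identical to the
#' mixture form (property-tested).  In the deaf limit the feedback term
#' vanishes exactly and \eqn{\Delta p = \epsilon}.
#'
#' @param p_f Encoded feedback pitch in cents (vectorized).
#' @param epsilon Current corrective bias in cents.
#' @param params A [model_params()] object.
#' @return Perceived deviation in cents, same length as `p_f`.
#' @export
perceived_deviation <- function(p_f, epsilon, params) {
  validate_model_params(params)
  if (!is.numeric(epsilon) || any(!is.finite(epsilon))) {
    abort("perceived_deviation: `epsilon` must be finite numeric",
          class = "pitchadapt_domain_error")
  }
  mu_m <- params$mu_target + epsilon
  if (is_deaf(params)) {
    if (self_locked(params) && !params$clamp_self) {
      abort("perceived_deviation: k = 0 in the deaf limit is degenerate (0/0)",
            class = "pitchadapt_degenerate_posterior")
    }
    return(rep(epsilon, length.out = max(length(p_f), length(epsilon))))
  }
  post <- self_posterior(p_f, mu_m, params)
  epsilon + (p_f - mu_m) * post * feedback_weight(params)
}

#' Simulate syllable renditions
#'
#' Draws `n` independent renditions at a given corrective bias and
#' feedback shift: produced pitch
#' \eqn{p \sim N(\mu^* + \epsilon, \sigma_m^2)}, encoded feedback
#' \eqn{p_f \sim N(p + p_\Delta, \sigma_f^2)}, then fills in the
#' self-source posterior and the perceived deviation per rendition.
#' Seeding is the caller's responsibility (wrap in
#' [withr::with_seed()] or `set.seed()` for reproducibility).
#'
#' @param n Number of renditions.
#' @param epsilon Corrective bias in cents.
#' @param p_shift Feedback shift \eqn{p_\Delta} in cents.
#' @param params A [model_params()] object.
#' @return A tibble with one row per rendition and columns `p`,
#'   `p_shift`, `p_ear`, `p_f`, `post_self`, `delta_p`.
#' @examples
#' params <- model_params(sigma_m = 46, sigma_f = 23, k = 1.5e-4)
#' withr::with_seed(1, sample_renditions(5, epsilon = 0, p_shift = 100, params))
#' @export
sample_renditions <- function(n, epsilon, p_shift, params) {
  validate_model_params(params)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1,
            is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon),
            is.numeric(p_shift), length(p_shift) == 1L, is.finite(p_shift))
  n <- as.integer(n)
  mu_m <- params$mu_target + epsilon
  p <- rnorm(n, mean = mu_m, sd = params$sigma_m)
  p_ear <- p + p_shift
  deaf <- is_deaf(params)
  if (deaf) {
    if (self_locked(params) && !params$clamp_self) {
      abort("sample_renditions: k = 0 in the deaf limit is degenerate (0/0)",
            class = "pitchadapt_degenerate_posterior")
    }
    ## feedback is pure noise: encoded value is unbounded, posterior is
    ## 0 (or 1 under the clamp) and the deviation reduces to epsilon
    noise <- rnorm(n)
    p_f <- p_ear + sign(noise) * Inf
    post <- rep(if (params$clamp_self) 1 else 0, n)
    delta_p <- rep(epsilon, n)
  } else {
    p_f <- rnorm(n, mean = p_ear, sd = params$sigma_f)
    post <- self_posterior(p_f, mu_m, params)
    delta_p <- epsilon + (p_f - mu_m) * post * feedback_weight(params)
  }
  tibble(p = p, p_shift = p_shift, p_ear = p_ear, p_f = p_f,
         post_self = post, delta_p = delta_p)
}
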