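#' Model parameters for the pitch-adaptation model
#'
#' Bundles every generative and inference parameter of the
#' causal-inference model of vocal pitch adaptation.  The vocalizer aims
#' at a pitch target `mu_target` (cents), produces renditions with motor
#' variability `sigma_m`, and hears them through a noisy auditory channel
#' with sensory noise `sigma_f`.  The constant `k` absorbs the prior odds
#' of an external sound source together with its (uniform) pitch
#' likelihood: larger `k` makes deviant feedback more readily attributed
#' to the environment and therefore ignored.
#'
#' `sigma_f = Inf` is the deaf limit: auditory feedback carries no
#' information, and the model predicts zero adaptation.  It is handled as
#' an exact limiting case throughout, never as a large float.
#'
#' `clamp_self = TRUE` forces the self-source posterior to 1 regardless
#' of `k`, modelling instructed subjects who must interpret all feedback
#' as self-caused.  It is behaviourally identical to `k = 0` but
#' numerically safe where the feedback likelihood underflows.
#'
#' @param mu_target Pitch target \eqn{\mu^*} in cents.  An arbitrary
#'   reference; all predictions are invariant to it.
#' @param sigma_m Motor (rendition-to-rendition) SD in cents, `> 0`.
#' @param sigma_f Sensory-feedback SD in cents, `>= 0`; `Inf` allowed.
#' @param k Dimensionless external-source constant, `>= 0`.
#' @param epsilon0 Read-out offset bias in cents, added to the corrective
#'   bias after equilibrium solving (a reporting bias, not dynamics).
#' @param clamp_self Logical; fix the self-source posterior at 1.
#'
#' @return An object of class `model_params` (a named list).
#' @examples
#' params <- model_params(sigma_m = 46, sigma_f = 23, k = 1.5e-4)
#' params
#' @export
model_params <- function(mu_target = 0, sigma_m = 46, sigma_f = 23,
                         k = 1.5e-4, epsilon0 = 0, clamp_self = FALSE) {
  p <- structure(
    list(mu_target = as.numeric(mu_target), sigma_m = as.numeric(sigma_m),
         sigma_f = as.numeric(sigma_f), k = as.numeric(k),
         epsilon0 = as.numeric(epsilon0), clamp_self = isTRUE(clamp_self)),
    class = "model_params")
  validate_model_params(p)
  p
}

validate_model_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  scalar_ok <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  for (nm in c("mu_target", "sigma_m", "sigma_f", "k", "epsilon0")) {
    if (!scalar_ok(p[[nm]])) {
      abort(sprintf("model_params: `%s` must be a non-missing numeric scalar", nm),
            class = "pitchadapt_domain_error")
    }
  }
  if (!is.finite(p$mu_target)) {
    abort("model_params: `mu_target` must be finite",
          class = "pitchadapt_domain_error")
  }
  if (!is.finite(p$sigma_m) || p$sigma_m <= 0) {
    abort("model_params: `sigma_m` must be finite and > 0",
          class = "pitchadapt_domain_error")
  }
  if (p$sigma_f < 0) {
    abort("model_params: `sigma_f` must be >= 0 (Inf allowed)",
          class = "pitchadapt_domain_error")
  }
  if (!is.finite(p$k) || p$k < 0) {
    abort("model_params: `k` must be finite and >= 0",
          class = "pitchadapt_domain_error")
  }
  if (!is.finite(p$epsilon0)) {
    abort("model_params: `epsilon0` must be finite",
          class = "pitchadapt_domain_error")
  }
  invisible(p)
}

#' Is the model in the deaf limit?
#'
#' @param params A [model_params()] object.
#' @return `TRUE` when `sigma_f` is infinite.
#' @export
is_deaf <- function(params) {
  validate_model_params(params)
  is.infinite(params$sigma_f)
}

## TRUE when the self-source posterior is pinned at 1 (clamp or k = 0)
self_locked <- function(params) params$clamp_self || params$k == 0

## prior weight of the feedback in the cue combination,
## sigma_m^2 / (sigma_f^2 + sigma_m^2); exactly 0 in the deaf limit
feedback_weight <- function(params) {
  if (is_deaf(params)) return(0)
  params$sigma_m^2 / (params$sigma_f^2 + params$sigma_m^2)
}

## SD of the self-feedback marginal, sqrt(sigma_f^2 + sigma_m^2)
combined_sd <- function(params) sqrt(params$sigma_f^2 + params$sigma_m^2)

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  mu_target : %g cents\n", x$mu_target))
  cat(sprintf("  sigma_m   : %g cents (motor SD)\n", x$sigma_m))
  cat(sprintf("  sigma_f   : %s (sensory SD)\n",
              if (is.infinite(x$sigma_f)) "Inf (deaf limit)"
              else paste0(format(x$sigma_f), " cents")))
  cat(sprintf("  k         : %g (external-source constant)\n", x$k))
  if (x$epsilon0 != 0) cat(sprintf("  epsilon0  : %g cents (read-out bias)\n", x$epsilon0))
  if (x$clamp_self) cat("  clamp_self: TRUE (P(self | feedback) fixed at 1)\n")
  invisible(x)
}

## update a params object with named replacements, re-validating
update_params <- function(params, ...) {
  repl <- list(...)
  p <- params
  for (nm in names(repl)) p[[nm]] <- repl[[nm]]
  validate_model_params(p)
  p
}
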