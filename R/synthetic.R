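#' Generate synthetic compensation datasets with known ground truth
#'
#' Runs the forward model (deterministic equilibrium solver) over a grid
#' and adds i.i.d. Gaussian observation noise to the percent-compensation
#' values, emulating a digitized published curve whose underlying
#' parameters are known exactly.  The generating parameters, noise SD
#' and seed are recorded in the dataset's metadata, so fitting routines
#' can be validated end-to-end without any external data.
#'
#' `obs_noise_sd` is deliberately a required argument: the noise level
#' is part of the experimental conditions being emulated, not a hidden
#' default.
#'
#' @param params Ground-truth [model_params()].
#' @param shifts Feedback shifts in cents (non-zero, finite).
#' @param sigma_m_grid Motor SDs in cents (positive, finite).
#' @param obs_noise_sd SD of additive Gaussian observation noise on the
#'   percent-compensation values (percent points, `>= 0`).
#' @param seed Integer seed; the dataset is fully reproducible.
#' @return A `compensation_dataset` tibble (see [compensation_dataset()])
#'   with `provenance = "synthetic"` and ground truth attached.
#' @examples
#' truth <- model_params(sigma_m = 46, sigma_f = 23, k = 1.5e-4)
#' make_shift_curve_dataset(truth, shifts = c(25, 50, 100), obs_noise_sd = 1, seed = 1)
#' @export
make_shift_curve_dataset <- function(params, shifts, obs_noise_sd, seed) {
  validate_model_params(params)
  stopifnot(length(shifts) >= 1, all(is.finite(shifts)), all(shifts != 0),
            is.numeric(obs_noise_sd), obs_noise_sd >= 0,
            is.numeric(seed), length(seed) == 1L)
  curve <- compensation_curve(params, shifts, method = "deterministic")
  noisy <- withr::with_seed(seed,
    curve$percent_compensation + rnorm(length(shifts), 0, obs_noise_sd))
  compensation_dataset(as.numeric(shifts), pmax(noisy, 0),
                       variable_kind = "shift_cents",
                       provenance = "synthetic", true_params = params,
                       obs_noise_sd = obs_noise_sd, seed = as.integer(seed))
}

#' @rdname make_shift_curve_dataset
#' @param p_shift Fixed feedback shift (cents) at which the motor-SD
#'   curve is generated.
#' @export
make_motor_sd_curve_dataset <- function(params, sigma_m_grid, obs_noise_sd, seed,
                                        p_shift = 100) {
  validate_model_params(params)
  stopifnot(length(sigma_m_grid) >= 1, all(is.finite(sigma_m_grid)),
            all(sigma_m_grid > 0),
            is.numeric(obs_noise_sd), obs_noise_sd >= 0,
            is.numeric(seed), length(seed) == 1L)
  curve <- compensation_vs_motor_variability(params, sigma_m_grid,
                                             p_shift = p_shift,
                                             method = "deterministic")
  noisy <- withr::with_seed(seed,
    curve$percent_compensation + rnorm(length(sigma_m_grid), 0, obs_noise_sd))
  compensation_dataset(as.numeric(sigma_m_grid), pmax(noisy, 0),
                       variable_kind = "motor_sd_cents",
                       provenance = "synthetic", true_params = params,
                       obs_noise_sd = obs_noise_sd, seed = as.integer(seed))
}
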