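## Compensation curves: tables of equilibrium results over a grid of one
## independent variable (shift, motor SD, or sensory SD).

solve_one <- function(p_shift, params, method, n_per_batch, eta, seed, ...) {
  if (method == "stochastic") {
    solve_equilibrium_stochastic(p_shift, params, n_per_batch = n_per_batch,
                                 eta = eta, seed = seed, ...)
  } else {
    solve_equilibrium_deterministic(p_shift, params)
  }
}

curve_tbl <- function(variable_kind, values, results, method) {
  out <- tibble(
    variable_kind = variable_kind,
    variable_value = values,
    p_shift_cents = purrr::map_dbl(results, "p_shift"),
    epsilon_cents = purrr::map_dbl(results, "epsilon"),
    percent_compensation = purrr::map_dbl(results, "percent_compensation"),
    method = method,
    seed = purrr::map_int(results, "seed"),
    converged = purrr::map_lgl(results, "converged"))
  class(out) <- c("compensation_tbl", class(out))
  out
}

#' Compensation curve over feedback shifts
#'
#' Solves the equilibrium corrective bias for each shift in `shifts` and
#' returns the percent-compensation curve
#' \eqn{c(p_\Delta) = 100\,|\epsilon + \epsilon_0| / |p_\Delta|}.  A
#' non-zero `epsilon0` in `params` is applied as a constant read-out
#' bias after solving, before the percent computation.  Rows with
#' `p_shift = 0` get `NA` compensation (the ratio is undefined).
#'
#' @param params A [model_params()] object.
#' @param shifts Feedback shifts in cents (non-empty, finite).
#' @param method `"deterministic"` (default, exact) or `"stochastic"`
#'   (the batch-sampling iteration).
#' @param n_per_batch,eta,seed Stochastic-solver settings; each shift
#'   uses `seed + position - 1` so rows are independent but reproducible.
#' @param ... Further arguments passed to the stochastic solver.
#' @return A `compensation_tbl` tibble with columns `variable_kind`,
#'   `variable_value`, `p_shift_cents`, `epsilon_cents`,
#'   `percent_compensation`, `method`, `seed`, `converged`.
#' @examples
#' params <- model_params(sigma_m = 46, sigma_f = 23, k = 1.5e-4)
#' compensation_curve(params, shifts = c(10, 30, 100, 300))
#' @export
compensation_curve <- function(params, shifts,
                               method = c("deterministic", "stochastic"),
                               n_per_batch = 200, eta = 0.001, seed = 1, ...) {
  validate_model_params(params)
  method <- match.arg(method)
  stopifnot(length(shifts) >= 1, all(is.finite(shifts)))
  res <- purrr::imap(as.numeric(shifts), function(pd, i) {
    r <- solve_one(pd, params, method, n_per_batch, eta, seed + i - 1L, ...)
    r$seed <- if (method == "stochastic") as.integer(seed + i - 1L) else NA_integer_
    r
  })
  curve_tbl("shift_cents", as.numeric(shifts), res, method)
}

#' Compensation as a function of motor variability
#'
#' Varies the motor SD over `sigma_m_grid` at a fixed shift and fixed
#' sensory parameters, reproducing the experimentally observed pattern
#' that more variable vocalizers compensate more.  Under `clamp_self`
#' the curve is the closed form
#' \eqn{c = 100\,\sigma_m^2 / (\sigma_m^2 + \sigma_f^2)}.
#'
#' @inheritParams compensation_curve
#' @param sigma_m_grid Motor SDs in cents (positive, finite).
#' @param p_shift Fixed feedback shift in cents.
#' @return A `compensation_tbl` with `variable_kind = "motor_sd_cents"`.
#' @export
compensation_vs_motor_variability <- function(params, sigma_m_grid, p_shift,
                                              method = c("deterministic", "stochastic"),
                                              n_per_batch = 200, eta = 0.001,
                                              seed = 1, ...) {
  validate_model_params(params)
  method <- match.arg(method)
  stopifnot(length(sigma_m_grid) >= 1, all(is.finite(sigma_m_grid)),
            all(sigma_m_grid > 0))
  res <- purrr::imap(as.numeric(sigma_m_grid), function(sm, i) {
    p <- update_params(params, sigma_m = sm)
    r <- solve_one(p_shift, p, method, n_per_batch, eta, seed + i - 1L, ...)
    r$seed <- if (method == "stochastic") as.integer(seed + i - 1L) else NA_integer_
    r
  })
  curve_tbl("motor_sd_cents", as.numeric(sigma_m_grid), res, method)
}

#' Compensation as a function of sensory noise
#'
#' Varies the sensory SD over `sigma_f_grid` at a fixed shift.  With an
#' external-source constant `k > 0` the curve is non-monotonic: very
#' reliable sensors reject deviant renditions as externally caused
#' (causal-inference outlier rejection), very noisy sensors are simply
#' distrusted, and compensation peaks at an intermediate noise level.
#' Infinite values in the grid are allowed and give exactly zero
#' compensation (deaf limit).
#'
#' @inheritParams compensation_curve
#' @param sigma_f_grid Sensory SDs in cents (`>= 0`; `Inf` allowed).
#' @param p_shift Fixed feedback shift in cents.
#' @return A `compensation_tbl` with `variable_kind = "sensory_sd_cents"`.
#' @export
compensation_vs_sensory_noise <- function(params, sigma_f_grid, p_shift,
                                          method = c("deterministic", "stochastic"),
                                          n_per_batch = 200, eta = 0.001,
                                          seed = 1, ...) {
  validate_model_params(params)
  method <- match.arg(method)
  stopifnot(length(sigma_f_grid) >= 1, all(sigma_f_grid >= 0),
            !any(is.na(sigma_f_grid)))
  res <- purrr::imap(as.numeric(sigma_f_grid), function(sf, i) {
    p <- update_params(params, sigma_f = sf)
    r <- solve_one(p_shift, p, method, n_per_batch, eta, seed + i - 1L, ...)
    r$seed <- if (method == "stochastic") as.integer(seed + i - 1L) else NA_integer_
    r
  })
  curve_tbl("sensory_sd_cents", as.numeric(sigma_f_grid), res, method)
}
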