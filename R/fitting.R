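#' Predict percent compensation for the points of a dataset
#'
#' Adds a `.pred` column with the model-predicted percent compensation
#' at each dataset point.  For `shift_cents` data the shift varies along
#' `x`; for `motor_sd_cents` data the motor SD varies along `x` at the
#' fixed `p_shift`.
#'
#' @param data A `compensation_dataset` (or conforming data frame).
#' @param params A [model_params()] object.
#' @param method Solver used for predictions: `"deterministic"` (exact)
#'   or `"stochastic"` (the sampling iteration).
#' @param p_shift Fixed shift for `motor_sd_cents` data, cents.
#' @param ... Passed to the stochastic solver when selected.
#' @return The dataset with a `.pred` column appended.
#' @export
predict_compensation <- function(data, params,
                                 method = c("deterministic", "stochastic"),
                                 p_shift = 100, ...) {
  validate_dataset(data)
  validate_model_params(params)
  method <- match.arg(method)
  kind <- dataset_kind(data)
  curve <- if (kind == "shift_cents") {
    compensation_curve(params, data$x, method = method, ...)
  } else {
    compensation_vs_motor_variability(params, data$x, p_shift = p_shift,
                                      method = method, ...)
  }
  out <- as_tibble(data)
  out$.pred <- curve$percent_compensation
  out
}

#' Mean absolute fitting residual
#'
#' Average absolute difference, in percent-compensation points, between
#' the model's predicted curve and the observed points of a dataset;
#' respects per-point weights when present.
#'
#' @inheritParams predict_compensation
#' @return Mean absolute residual (percent points).
#' @examples
#' truth <- model_params(sigma_m = 46, sigma_f = 23, k = 1.5e-4)
#' d <- make_shift_curve_dataset(truth, c(25, 50, 100), obs_noise_sd = 0, seed = 1)
#' compensation_residual(d, truth)  # ~0: self-consistency
#' @export
compensation_residual <- function(data, params,
                                  method = c("deterministic", "stochastic"),
                                  p_shift = 100, ...) {
  pred <- predict_compensation(data, params, method = method,
                               p_shift = p_shift, ...)
  err <- abs(pred$.pred - pred$c)
  if ("weight" %in% names(pred)) {
    sum(pred$weight * err) / sum(pred$weight)
  } else {
    mean(err)
  }
}

fittable <- c("sigma_f", "k", "sigma_m", "epsilon0")

#' Fit model parameters by greedy random search
#'
#' Random-search residual minimization: starting from `init`, propose
#' new values for the free parameters -- multiplicatively, log-uniform
#' within a factor of `[0.1, 10]` of the current best for the positive
#' scale parameters (`sigma_f`, `k`, `sigma_m`), and additively, uniform
#' within `±epsilon0_halfwidth` cents for `epsilon0`, which may be zero
#' or negative -- and accept a proposal only if the residual strictly
#' decreases.  After `budget` proposals the best state is returned.
#' `k` proposals are floored at `1e-320` so the search can reach the
#' essentially-`k = 0` regime without leaving log space.
#'
#' The acceptance rule is greedy, so the search can stall in a local
#' minimum; `n_restarts > 1` reruns it from random initial points
#' (log-uniform `sigma_f` in `[0.5, 100]` cents, `k` in
#' `[1e-16, 1e-2]`, `sigma_m` in `[5, 100]` cents, `epsilon0 = 0`) and
#' keeps the best run.  Everything is reproducible under `seed`.
#'
#' @param data A `compensation_dataset` with at least 2 points.
#' @param init [model_params()] giving the starting point and the values
#'   of every fixed parameter (including `clamp_self`).
#' @param free Character vector of parameters to search, a subset of
#'   `"sigma_f"`, `"k"`, `"sigma_m"`, `"epsilon0"`.
#' @param budget Number of proposals per restart (`>= 1`).
#' @param seed Integer seed.
#' @param epsilon0_halfwidth Half-width of additive `epsilon0`
#'   proposals, cents.
#' @param n_restarts Number of independent restarts (first one starts
#'   from `init`).
#' @param method Objective engine: `"deterministic"` (default, stable)
#'   or `"stochastic"` for fidelity to the all-sampling loop.
#' @param p_shift Fixed shift for `motor_sd_cents` data, cents.
#' @param ... Passed to the stochastic solver when selected.
#' @return A `pitch_fit` object: best parameters, residual, full
#'   proposal trace; see [tidy.pitch_fit()].
#' @examples
#' truth <- model_params(sigma_m = 46, sigma_f = 23, k = 1.5e-4)
#' d <- make_shift_curve_dataset(truth, c(10, 30, 50, 100, 150, 200, 300),
#'                               obs_noise_sd = 1, seed = 1)
#' fit <- fit_random_search(d, init = model_params(sigma_m = 46, sigma_f = 10, k = 1e-3),
#'                          free = c("sigma_f", "k"), budget = 200, seed = 1)
#' glance(fit)
#' @export
fit_random_search <- function(data, init = model_params(),
                              free = c("sigma_f", "k"), budget = 500, seed = 1,
                              epsilon0_halfwidth = 20, n_restarts = 1,
                              method = c("deterministic", "stochastic"),
                              p_shift = 100, ...) {
  validate_dataset(data, min_points = 2L)
  validate_model_params(init)
  method <- match.arg(method)
  stopifnot(budget >= 1, n_restarts >= 1, epsilon0_halfwidth > 0)
  free <- match.arg(free, fittable, several.ok = TRUE)
  if (init$clamp_self && "k" %in% free) {
    abort("fit_random_search: `k` has no effect under clamp_self; drop it from `free`",
          class = "pitchadapt_domain_error")
  }

  objective <- function(params) {
    compensation_residual(data, params, method = method, p_shift = p_shift, ...)
  }

  run_one <- function(start, run_seed, restart_id) {
    best <- start
    best_resid <- objective(best)
    rows <- vector("list", budget + 1L)
    rows[[1L]] <- c(step = 0, restart = restart_id,
                    sigma_f = best$sigma_f, k = best$k, sigma_m = best$sigma_m,
                    epsilon0 = best$epsilon0, residual = best_resid, accepted = 1)
    withr::with_seed(run_seed, {
      for (i in seq_len(budget)) {
        prop <- best
        for (par in free) {
          if (par == "epsilon0") {
            prop$epsilon0 <- best$epsilon0 + runif(1, -epsilon0_halfwidth,
                                                   epsilon0_halfwidth)
          } else {
            prop[[par]] <- best[[par]] * 10^runif(1, -1, 1)
          }
        }
        if ("k" %in% free) prop$k <- max(prop$k, 1e-320)
        resid <- objective(prop)
        accept <- resid < best_resid
        if (accept) {
          best <- prop
          best_resid <- resid
        }
        rows[[i + 1L]] <- c(step = i, restart = restart_id,
                            sigma_f = prop$sigma_f, k = prop$k,
                            sigma_m = prop$sigma_m, epsilon0 = prop$epsilon0,
                            residual = resid, accepted = as.numeric(accept))
      }
    })
    trace <- as_tibble(do.call(rbind, rows))
    trace$accepted <- trace$accepted == 1
    list(best = best, residual = best_resid, trace = trace)
  }

  runs <- withr::with_seed(seed, {
    run_seeds <- sample.int(.Machine$integer.max - 1L, n_restarts)
    starts <- vector("list", n_restarts)
    starts[[1L]] <- init
    if (n_restarts > 1L) {
      for (r in 2:n_restarts) {
        st <- init
        if ("sigma_f" %in% free) st$sigma_f <- exp(runif(1, log(0.5), log(100)))
        if ("k" %in% free)       st$k <- 10^runif(1, -16, -2)
        if ("sigma_m" %in% free) st$sigma_m <- exp(runif(1, log(5), log(100)))
        if ("epsilon0" %in% free) st$epsilon0 <- 0
        starts[[r]] <- st
      }
    }
    purrr::map2(starts, seq_len(n_restarts),
                function(st, r) run_one(st, run_seeds[r], r))
  })

  best_run <- runs[[which.min(purrr::map_dbl(runs, "residual"))]]
  structure(
    list(params = best_run$best, residual = best_run$residual,
         free = free, init = init, budget = as.integer(budget),
         n_restarts = as.integer(n_restarts), seed = as.integer(seed),
         method = method,
         n_accepted = as.integer(
           sum(purrr::map_int(runs, ~ sum(.x$trace$accepted))) - n_restarts),
         trace = dplyr::bind_rows(purrr::map(runs, "trace")),
         data = data),
    class = "pitch_fit")
}

#' Fit a named model variant
#'
#' Configures the free-parameter mask for the model variants used in
#' practice and dispatches to [fit_random_search()] with multi-start
#' defaults:
#'
#' * `"full"` -- frees `sigma_f` and `k` (the two-parameter causal
#'   inference model).
#' * `"with_offset"` -- additionally frees the read-out bias `epsilon0`,
#'   for datasets whose compensation estimates carry a constant additive
#'   bias (e.g. peak-based response measures).
#' * `"clamped_self"` -- fixes the self-source posterior at 1 and frees
#'   only `sigma_f`, the one-parameter instructed-subject model.
#'
#' `free_sigma_m = TRUE` adds the motor SD to the mask of any variant
#' (for datasets whose motor variability was not reported).
#'
#' @inheritParams fit_random_search
#' @param variant One of `"full"`, `"with_offset"`, `"clamped_self"`.
#' @param free_sigma_m Also fit the motor SD?
#' @return A `pitch_fit` object.
#' @export
fit_variants <- function(data, variant = c("full", "with_offset", "clamped_self"),
                         init = model_params(), free_sigma_m = FALSE,
                         budget = 1000, seed = 1, n_restarts = 4, ...) {
  variant <- match.arg(variant)
  free <- switch(variant,
                 full = c("sigma_f", "k"),
                 with_offset = c("sigma_f", "k", "epsilon0"),
                 clamped_self = "sigma_f")
  if (free_sigma_m) free <- c(free, "sigma_m")
  init$clamp_self <- variant == "clamped_self"
  validate_model_params(init)
  fit <- fit_random_search(data, init = init, free = free, budget = budget,
                           seed = seed, n_restarts = n_restarts, ...)
  fit$variant <- variant
  fit
}

#' @export
print.pitch_fit <- function(x, ...) {
  cat("<pitch_fit>\n")
  if (!is.null(x$variant)) cat(sprintf("  variant : %s\n", x$variant))
  cat(sprintf("  free    : %s\n", paste(x$free, collapse = ", ")))
  est <- x$params
  cat(sprintf("  sigma_f : %g cents%s\n", est$sigma_f,
              if ("sigma_f" %in% x$free) "" else " (fixed)"))
  cat(sprintf("  k       : %g%s\n", est$k,
              if ("k" %in% x$free) "" else if (est$clamp_self) " (clamped)" else " (fixed)"))
  cat(sprintf("  sigma_m : %g cents%s\n", est$sigma_m,
              if ("sigma_m" %in% x$free) "" else " (fixed)"))
  if (est$epsilon0 != 0 || "epsilon0" %in% x$free) {
    cat(sprintf("  epsilon0: %g cents%s\n", est$epsilon0,
                if ("epsilon0" %in% x$free) "" else " (fixed)"))
  }
  cat(sprintf("  residual: %.4f percent points (%d/%d proposals accepted)\n",
              x$residual, x$n_accepted, x$budget * x$n_restarts))
  invisible(x)
}

#' Tidy a random-search fit
#'
#' @param x A `pitch_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per model parameter: `term`,
#'   `estimate`, and whether it was `free` during the search.
#' @export
tidy.pitch_fit <- function(x, ...) {
  tibble(term = fittable,
         estimate = c(x$params$sigma_f, x$params$k, x$params$sigma_m,
                      x$params$epsilon0),
         free = fittable %in% x$free)
}

#' One-row summary of a random-search fit
#'
#' @param x A `pitch_fit` object.
#' @param ... Unused.
#' @export
glance.pitch_fit <- function(x, ...) {
  tibble(residual = x$residual, n_points = nrow(x$data),
         n_accepted = x$n_accepted, budget = x$budget,
         n_restarts = x$n_restarts, seed = x$seed, method = x$method,
         clamp_self = x$params$clamp_self)
}

#' Dataset with fitted predictions attached
#'
#' @param x A `pitch_fit` object.
#' @param ... Unused.
#' @return The fitted dataset with a `.pred` column.
#' @export
augment.pitch_fit <- function(x, ...) {
  predict_compensation(x$data, x$params, method = "deterministic")
}

#' Write a fit report and search trace
#'
#' Writes the fitted parameters and settings as a flat `key = value`
#' report, and the full proposal trace as CSV next to it
#' (`<path>.trace.csv`).
#'
#' @param fit A `pitch_fit` object.
#' @param path Report file path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "pitch_fit"))
  est <- fit$params
  kv <- c(variant = fit$variant %||% "custom",
          free = paste(fit$free, collapse = ","),
          sigma_f = format(est$sigma_f, digits = 17),
          k = format(est$k, digits = 17),
          sigma_m = format(est$sigma_m, digits = 17),
          epsilon0 = format(est$epsilon0, digits = 17),
          clamp_self = as.character(est$clamp_self),
          residual = format(fit$residual, digits = 17),
          n_accepted = as.character(fit$n_accepted),
          budget = as.character(fit$budget),
          n_restarts = as.character(fit$n_restarts),
          seed = as.character(fit$seed),
          method = fit$method)
  writeLines(paste(names(kv), kv, sep = " = "), path)
  readr::write_csv(fit$trace, paste0(path, ".trace.csv"))
  invisible(path)
}
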