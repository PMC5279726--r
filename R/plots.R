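## ggplot2 quick-look figures for each result type

axis_label <- function(kind) {
  switch(kind,
         shift_cents = "feedback shift (cents)",
         motor_sd_cents = "motor SD (cents)",
         sensory_sd_cents = "sensory SD (cents)",
         kind)
}

#' Plot a solved compensation curve
#'
#' @param object A `compensation_tbl` from [compensation_curve()] and
#'   friends.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.compensation_tbl <- function(object, ...) {
  kind <- unique(object$variable_kind)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$variable_value,
                               y = .data$percent_compensation)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = axis_label(kind), y = "percent compensation") +
    ggplot2::theme_minimal()
}

#' Plot a compensation dataset
#'
#' @param object A `compensation_dataset`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.compensation_dataset <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$c)) +
    ggplot2::geom_point(shape = 4) +
    ggplot2::labs(x = axis_label(dataset_kind(object)),
                  y = "percent compensation") +
    ggplot2::theme_minimal()
}

#' Plot the batch trajectory of a stochastic equilibrium run
#'
#' @param object A `pitch_equilibrium` object.
#' @param ... Unused.
#' @return A ggplot; for deterministic results a single horizontal line.
#' @export
autoplot.pitch_equilibrium <- function(object, ...) {
  if (is.null(object$trajectory)) {
    df <- tibble(batch = c(0, 1), epsilon = object$epsilon)
  } else {
    df <- tibble(batch = seq_along(object$trajectory),
                 epsilon = object$trajectory)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$batch, y = .data$epsilon)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$epsilon, linetype = "dashed") +
    ggplot2::labs(x = "batch", y = "corrective bias (cents)") +
    ggplot2::theme_minimal()
}

#' Plot a fit: observed points with the fitted curve
#'
#' @param object A `pitch_fit` object.
#' @param n_grid Number of grid points for the fitted curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pitch_fit <- function(object, n_grid = 60, ...) {
  data <- object$data
  kind <- dataset_kind(data)
  grid <- seq(min(data$x), max(data$x), length.out = n_grid)
  curve <- if (kind == "shift_cents") {
    compensation_curve(object$params, grid[grid != 0])
  } else {
    compensation_vs_motor_variability(object$params, grid, p_shift = 100)
  }
  ggplot2::ggplot() +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$variable_value,
                                    y = .data$percent_compensation)) +
    ggplot2::geom_point(data = as_tibble(data),
                        ggplot2::aes(x = .data$x, y = .data$c), shape = 4) +
    ggplot2::labs(x = axis_label(kind), y = "percent compensation") +
    ggplot2::theme_minimal()
}
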