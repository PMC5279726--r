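#' Compensation datasets
#'
#' A compensation dataset is the fitting currency of the package: a
#' table of points `(x, c)` where `x` is either a feedback shift or a
#' motor SD (both in cents, per `variable_kind`) and `c` is the observed
#' percent compensation.  Datasets come from the synthetic generators
#' ([make_shift_curve_dataset()], [make_motor_sd_curve_dataset()]) or
#' from user-digitized published figures read with
#' [read_compensation_csv()].
#'
#' @param x Independent variable, cents (finite).
#' @param c Percent compensation (`>= 0`).
#' @param variable_kind `"shift_cents"` or `"motor_sd_cents"`.
#' @param weight Optional positive per-point fitting weights.
#' @param provenance `"synthetic"` or `"user-digitized"`.
#' @param true_params Ground-truth [model_params()] for synthetic data,
#'   else `NULL`.
#' @param obs_noise_sd Observation-noise SD used by the generator
#'   (percent points), else `NA`.
#' @param seed Generator seed, else `NA`.
#' @return A tibble of class `compensation_dataset` with columns
#'   `variable_kind`, `x`, `c` (and `weight` if given); generator
#'   metadata is attached as attributes.
#' @export
compensation_dataset <- function(x, c, variable_kind = c("shift_cents", "motor_sd_cents"),
                                 weight = NULL,
                                 provenance = c("user-digitized", "synthetic"),
                                 true_params = NULL, obs_noise_sd = NA_real_,
                                 seed = NA_integer_) {
  variable_kind <- match.arg(variable_kind)
  provenance <- match.arg(provenance)
  stopifnot(is.numeric(x), is.numeric(c), length(x) == length(c),
            all(is.finite(x)), all(is.finite(c)))
  if (any(c < 0)) {
    abort("compensation_dataset: percent compensation must be >= 0",
          class = "pitchadapt_domain_error")
  }
  if (variable_kind == "shift_cents" && any(x == 0)) {
    abort("compensation_dataset: zero shifts have undefined percent compensation",
          class = "pitchadapt_domain_error")
  }
  if (variable_kind == "motor_sd_cents" && any(x <= 0)) {
    abort("compensation_dataset: motor SDs must be > 0",
          class = "pitchadapt_domain_error")
  }
  out <- tibble(variable_kind = variable_kind, x = as.numeric(x), c = as.numeric(c))
  if (!is.null(weight)) {
    stopifnot(is.numeric(weight), length(weight) == length(x),
              all(is.finite(weight)), all(weight > 0))
    out$weight <- as.numeric(weight)
  }
  if (!is.null(true_params)) validate_model_params(true_params)
  structure(out,
            class = c("compensation_dataset", class(out)),
            provenance = provenance, true_params = true_params,
            obs_noise_sd = obs_noise_sd, seed = seed)
}

dataset_kind <- function(data) {
  kind <- unique(as.character(data$variable_kind))
  if (length(kind) != 1L || !kind %in% c("shift_cents", "motor_sd_cents")) {
    abort("dataset must have a single variable_kind of 'shift_cents' or 'motor_sd_cents'",
          class = "pitchadapt_schema_error")
  }
  kind
}

validate_dataset <- function(data, min_points = 1L) {
  if (!is.data.frame(data) || !all(c("variable_kind", "x", "c") %in% names(data))) {
    abort("dataset must be a data frame with columns variable_kind, x, c",
          class = "pitchadapt_schema_error")
  }
  if (nrow(data) < min_points) {
    abort(sprintf("dataset must have at least %d points", min_points),
          class = "pitchadapt_schema_error")
  }
  if (!is.numeric(data$x) || !is.numeric(data$c) ||
      any(!is.finite(data$x)) || any(!is.finite(data$c))) {
    abort("dataset columns x and c must be finite numeric",
          class = "pitchadapt_schema_error")
  }
  dataset_kind(data)
  invisible(data)
}

#' Convert a solved compensation curve to a fitting dataset
#'
#' Drops solver diagnostics from a `compensation_tbl` (see
#' [compensation_curve()]) keeping the `(x, c)` points, so model-derived
#' curves can be fed back into the fitting routines.
#'
#' @param curve A `compensation_tbl`.
#' @param provenance Provenance tag for the resulting dataset.
#' @return A `compensation_dataset` tibble.
#' @export
as_compensation_dataset <- function(curve, provenance = "synthetic") {
  stopifnot(inherits(curve, "compensation_tbl"))
  kind <- unique(curve$variable_kind)
  stopifnot(length(kind) == 1L)
  if (kind == "sensory_sd_cents") {
    abort("sensory-noise curves are predictions, not fitting datasets",
          class = "pitchadapt_domain_error")
  }
  keep <- !is.na(curve$percent_compensation)
  compensation_dataset(curve$variable_value[keep],
                       curve$percent_compensation[keep],
                       variable_kind = kind, provenance = provenance)
}

#' Read and write compensation datasets as CSV
#'
#' Plain UTF-8 comma-separated files with a mandatory header and columns
#' `variable_kind`, `x`, `c` and optionally `weight`.  [write_compensation_csv()]
#' also writes a sidecar key-value file `<path>.meta` carrying the
#' provenance tag and, for synthetic data, the generator's ground-truth
#' parameters; [read_compensation_csv()] restores it when present.
#' Write--read round-trips reproduce the dataset exactly.
#'
#' @param data A `compensation_dataset` (or conforming data frame).
#' @param path CSV file path.
#' @return `read_compensation_csv()` returns a `compensation_dataset`;
#'   `write_compensation_csv()` returns `path` invisibly.
#' @export
write_compensation_csv <- function(data, path) {
  validate_dataset(data)
  cols <- intersect(c("variable_kind", "x", "c", "weight"), names(data))
  readr::write_csv(as_tibble(data)[cols], path)
  meta <- c(provenance = attr(data, "provenance") %||% "user-digitized")
  tp <- attr(data, "true_params")
  if (!is.null(tp)) {
    meta <- c(meta,
              true_mu_target = format(tp$mu_target, digits = 17),
              true_sigma_m = format(tp$sigma_m, digits = 17),
              true_sigma_f = format(tp$sigma_f, digits = 17),
              true_k = format(tp$k, digits = 17),
              true_epsilon0 = format(tp$epsilon0, digits = 17),
              true_clamp_self = as.character(tp$clamp_self))
  }
  if (!is.na(attr(data, "obs_noise_sd") %||% NA)) {
    meta <- c(meta, obs_noise_sd = format(attr(data, "obs_noise_sd"), digits = 17))
  }
  if (!is.na(attr(data, "seed") %||% NA)) {
    meta <- c(meta, seed = as.character(attr(data, "seed")))
  }
  writeLines(paste(names(meta), meta, sep = " = "), paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_compensation_csv
#' @export
read_compensation_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("variable_kind", "x", "c") %in% names(df))) {
    abort(sprintf("malformed dataset CSV '%s': need columns variable_kind, x, c", path),
          class = "pitchadapt_schema_error")
  }
  validate_dataset(df)
  meta_path <- paste0(path, ".meta")
  provenance <- "user-digitized"
  true_params <- NULL
  obs_noise_sd <- NA_real_
  seed <- NA_integer_
  if (file.exists(meta_path)) {
    kv <- read_keyvalue(meta_path)
    provenance <- kv[["provenance"]] %||% provenance
    if (!is.null(kv[["true_sigma_m"]])) {
      true_params <- model_params(
        mu_target = as.numeric(kv[["true_mu_target"]] %||% 0),
        sigma_m = as.numeric(kv[["true_sigma_m"]]),
        sigma_f = as.numeric(kv[["true_sigma_f"]]),
        k = as.numeric(kv[["true_k"]]),
        epsilon0 = as.numeric(kv[["true_epsilon0"]] %||% 0),
        clamp_self = identical(kv[["true_clamp_self"]], "TRUE"))
    }
    if (!is.null(kv[["obs_noise_sd"]])) obs_noise_sd <- as.numeric(kv[["obs_noise_sd"]])
    if (!is.null(kv[["seed"]])) seed <- as.integer(kv[["seed"]])
  }
  compensation_dataset(df$x, df$c, variable_kind = dataset_kind(df),
                       weight = df[["weight"]],
                       provenance = provenance, true_params = true_params,
                       obs_noise_sd = obs_noise_sd, seed = seed)
}

## flat "key = value" config / metadata files
read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) {
    abort(sprintf("malformed key-value line in '%s': %s", path, lines[bad][1]),
          class = "pitchadapt_schema_error")
  }
  vals <- lapply(kv, function(p) trimws(paste(p[-1], collapse = "=")))
  setNames(vals, vapply(kv, function(p) trimws(p[1]), character(1)))
}

#' Write a solved compensation curve to CSV
#'
#' Serializes a `compensation_tbl` (see [compensation_curve()]) with its
#' full diagnostic columns.
#'
#' @param curve A `compensation_tbl`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_equilibrium_csv <- function(curve, path) {
  stopifnot(inherits(curve, "compensation_tbl"))
  readr::write_csv(as_tibble(curve), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
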