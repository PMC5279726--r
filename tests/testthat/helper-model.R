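# shared fixtures: everything is generated in code, no stored data

finch_params <- function(...) {
  # best-fit regime for the songbird compensation curve
  model_params(sigma_m = 46, sigma_f = 23, k = 1.5e-4, ...)
}

# closed-form equilibrium when the self posterior is pinned at 1
closed_form_eps <- function(p_shift, sigma_m, sigma_f) {
  -p_shift * sigma_m^2 / (sigma_m^2 + sigma_f^2)
}

# minimal reader for the flat "key = value" report files
read_keyvalue_for_test <- function(path) {
  lines <- trimws(readLines(path))
  kv <- strsplit(lines[nzchar(lines)], " = ", fixed = TRUE)
  stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
}

# random but reproducible (sigma_m, sigma_f, p_shift) triples
random_triples <- function(n, seed = 42) {
  withr::with_seed(seed, {
    tibble::tibble(sigma_m = runif(n, 10, 60),
                   sigma_f = runif(n, 0, 40),
                   p_shift = sample(c(-1, 1), n, replace = TRUE) * runif(n, 20, 250))
  })
}
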