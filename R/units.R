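#' Pitch unit conversions
#'
#' Cents are a logarithmic pitch scale relative to an arbitrary
#' reference: `p = 1200 * log2(F) - kappa` for a fundamental frequency
#' `F` in Hz.  100 cents is a semitone, 1200 cents an octave.  The
#' reference `kappa` never enters any model computation; it only anchors
#' conversions back to Hz.
#'
#' @param f_hz Fundamental frequency in Hz (`> 0`).
#' @param p Pitch in cents.
#' @param kappa Reference offset in cents.
#' @return `hz_to_cents()` returns cents; `cents_to_hz()` returns Hz.
#'   The two are exact inverses.
#' @examples
#' hz_to_cents(880) - hz_to_cents(440)  # one octave = 1200 cents
#' @export
hz_to_cents <- function(f_hz, kappa = 0) {
  stopifnot(is.numeric(f_hz), all(f_hz > 0), is.finite(kappa))
  1200 * log2(f_hz) - kappa
}

#' @rdname hz_to_cents
#' @export
cents_to_hz <- function(p, kappa = 0) {
  stopifnot(is.numeric(p), all(is.finite(p)), is.finite(kappa))
  2^((p + kappa) / 1200)
}

#' Convert a median absolute deviation to a Gaussian SD
#'
#' Multiplies by the consistency constant 1.4826 that relates the MAD of
#' a Gaussian to its standard deviation.  Published pitch-variability
#' tables often report MADs; the model's `sigma_m` is a Gaussian SD.
#'
#' @param mad Median absolute deviation (cents, `>= 0`).
#' @return SD in cents.
#' @examples
#' mad_to_sd(31)  # ~46 cents
#' @export
mad_to_sd <- function(mad) {
  stopifnot(is.numeric(mad), all(mad >= 0), all(is.finite(mad)))
  mad * 1.4826
}
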