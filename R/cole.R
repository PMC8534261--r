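#' Default measurement frequency grid
#'
#' The wearable sweeps 20 kHz to 500 kHz in 20 kHz steps, giving 25
#' frequencies per channel.
#'
#' @param from,to,by grid limits and step in Hz.
#' @return numeric vector of strictly increasing positive frequencies (Hz).
#' @export
#' @examples
#' length(frequency_grid()) # 25
frequency_grid <- function(from = 20e3, to = 500e3, by = 20e3) {
  grid <- seq(from, to, by = by)
  if (any(grid <= 0) || is.unsorted(grid, strictly = TRUE)) {
    stop("frequency grid must be positive and strictly increasing")
  }
  grid
}

#' Single-dispersion Cole tissue-impedance parameters
#'
#' The latent per-tissue spectrum is the classic Cole model
#' \eqn{Z(f) = R_\infty + (R_0 - R_\infty) / (1 + (i f / f_c)^\alpha)},
#' with low- and high-frequency resistances `r0 > r_inf > 0`, characteristic
#' frequency `fc` and broadening exponent `alpha` in (0, 1].
#'
#' @param r_inf high-frequency resistance (ohm).
#' @param r0 low-frequency resistance (ohm); must exceed `r_inf`.
#' @param fc characteristic frequency (Hz).
#' @param alpha dispersion broadening exponent in (0, 1].
#' @return an object of class `cole_params`.
#' @export
cole_params <- function(r_inf, r0, fc, alpha) {
  if (!is.numeric(r_inf) || !is.numeric(r0) || !is.numeric(fc) ||
      !is.numeric(alpha)) {
    stop("cole parameters must be numeric")
  }
  if (r_inf <= 0) stop("r_inf must be positive")
  if (r0 <= r_inf) stop("r0 must exceed r_inf")
  if (fc <= 0) stop("fc must be positive")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  structure(list(r_inf = r_inf, r0 = r0, fc = fc, alpha = alpha),
            class = "cole_params")
}

#' Cole impedance magnitude over a frequency grid
#'
#' Evaluates the magnitude of the complex Cole expression at each grid
#' frequency. The device stores RMS-derived magnitudes, so all downstream
#' analysis operates on real, positive ohm values; phase is never simulated.
#'
#' @param params a [cole_params()] object.
#' @param grid numeric vector of positive frequencies (Hz).
#' @return numeric vector of impedance magnitudes (ohm), one per frequency,
#'   non-increasing in frequency and bounded by `[r_inf, r0]`.
#' @export
#' @examples
#' cole_magnitude(cole_params(100, 300, 1e5, 1), 1e5) # |100 + 200/(1+i)|
cole_magnitude <- function(params, grid) {
  stopifnot(inherits(params, "cole_params"))
  if (any(grid <= 0)) stop("frequencies must be positive")
  z <- params$r_inf +
    (params$r0 - params$r_inf) /
      (1 + (1i * grid / params$fc)^params$alpha)
  Mod(z)
}
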