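#' Simulate a multi-echo magnitude signal
#'
#' Mono-exponential ROI-mean magnitude decay \eqn{S(TE) = S_0 e^{-TE/T2*}}
#' sampled on the protocol's TE schedule. With `noise_sigma > 0` each
#' sample is Rician: the modulus of the noiseless signal plus independent
#' zero-mean Gaussian noise of sd `noise_sigma` in each of the two complex
#' channels. Rician noise is what creates the positive noise floor at long
#' TE that the truncation method exists to mitigate. `noise_model =
#' "gaussian"` adds plain real Gaussian noise instead (useful in unit
#' tests where an unbiased noise model is wanted).
#'
#' @param s0 baseline amplitude (> 0), arbitrary units.
#' @param t2star effective transverse relaxation time in ms (> 0).
#' @param protocol an [acquisition_protocol()].
#' @param noise_sigma channel noise standard deviation (>= 0).
#' @param noise_model `"rician"` (default) or `"gaussian"`.
#' @return An [echo_train()] with the protocol's TEs and the simulated
#'   magnitudes.
#' @examples
#' simulate_echo_train(1000, 5)$signal[1]  # 1000 * exp(-1.29 / 5)
#' @export
simulate_echo_train <- function(s0, t2star, protocol = acquisition_protocol(),
                                noise_sigma = 0,
                                noise_model = c("rician", "gaussian")) {
  noise_model <- match.arg(noise_model)
  if (!is.numeric(s0) || length(s0) != 1L || !is.finite(s0) || s0 <= 0) {
    stop("s0 must be finite and > 0", call. = FALSE)
  }
  if (!is.numeric(t2star) || length(t2star) != 1L ||
      is.na(t2star) || t2star <= 0) {
    stop("t2star must be > 0", call. = FALSE)
  }
  stopifnot(noise_sigma >= 0)
  te <- protocol$te_schedule
  nu <- s0 * exp(-te / t2star)
  if (noise_sigma == 0) {
    signal <- nu
  } else if (noise_model == "rician") {
    g1 <- stats::rnorm(length(te), 0, noise_sigma)
    g2 <- stats::rnorm(length(te), 0, noise_sigma)
    signal <- sqrt((nu + g1)^2 + g2^2)
  } else {
    # magnitudes stay nonnegative; clamping only matters deep in the floor
    signal <- pmax(nu + stats::rnorm(length(te), 0, noise_sigma), 0)
  }
  echo_train(te, signal)
}
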