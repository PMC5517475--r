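#' Multiphoton excitation and detection
#'
#' The physical core of the chain: a pixel of sample strength X excited at
#' power P emits, on average, \eqn{X P^\alpha} detected photoelectrons per
#' dwell sub-sample (plus dark counts).  With shot noise enabled the detected
#' count is a Poisson draw; the detector saturates (clips) at `cfg$S_sat`.
#'
#' @param X Sample strength (>= 0); vectorized.
#' @param P_actual Illumination power at the sample, normalized units (>= 0).
#' @param cfg An [acquisition_config()].
#' @param noise A [noise_model()].
#' @return A list with `S` (detected photoelectrons, clipped at `S_sat`) and
#'   `clipped` (logical: detector saturated).
#' @examples
#' cfg <- acquisition_config()
#' excite_and_detect(1, 2, cfg, noise_model(shot_noise = FALSE))$S  # 4
#' @export
excite_and_detect <- function(X, P_actual, cfg, noise = noise_model()) {
  if (any(X < 0) || any(P_actual < 0)) {
    stop("`X` and `P_actual` must be >= 0", call. = FALSE)
  }
  lambda <- X * P_actual^cfg$alpha + noise$dark_rate
  S <- if (noise$shot_noise) stats::rpois(length(lambda), lambda) else lambda
  clipped <- S >= cfg$S_sat
  S[clipped] <- cfg$S_sat
  list(S = S, clipped = clipped)
}

#' Digitize the detected signal
#'
#' Applies the signal ADC gain \eqn{G_S = 2^{B_S}/S_{sat}} (nominally filling
#' the converter bit depth minus one at saturation) and rounds to an integer
#' code, clipping to the code range.
#'
#' @param S Detected photoelectrons (>= 0); vectorized.
#' @param cfg An [acquisition_config()].
#' @return List with `S_hat` (integer codes in `[0, 2^B_S - 1]`) and
#'   `clipped` (logical: code clipped high).
#' @examples
#' cfg <- acquisition_config()
#' quantize_signal(125, cfg)$S_hat   # 4096
#' quantize_signal(250, cfg)         # clips at 8191
#' @export
quantize_signal <- function(S, cfg) {
  if (any(S < 0)) stop("`S` must be >= 0", call. = FALSE)
  code <- round(cfg$G_S * S)
  clipped <- code > cfg$S_max_code
  code[clipped] <- cfg$S_max_code
  list(S_hat = code, clipped = clipped)
}

#' Electro-optic modulator response
#'
#' First-order relaxation of the actual power toward the commanded power,
#' optionally distorted by a weak quadratic response at low command levels.
#' With `eom_tau = 0` the actuator is instantaneous.
#'
#' @param P_command Commanded power, normalized (in `[0, P_max]`).
#' @param P_prev_actual Actual power at the previous sub-step.
#' @param dt Time step, s (> 0).
#' @param noise A [noise_model()] supplying `eom_tau`, `eom_quad` and
#'   `eom_quad_threshold`.
#' @return Actual power after `dt`.
#' @examples
#' apply_eom(1, 0, dt = 1e-7, noise_model(eom_tau = 0))      # 1
#' apply_eom(1, 0, dt = 5e-7, noise_model(eom_tau = 1e-7))   # within 1% of 1
#' @export
apply_eom <- function(P_command, P_prev_actual, dt, noise = noise_model()) {
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  target <- P_command
  low <- P_command < noise$eom_quad_threshold
  if (noise$eom_quad > 0 && any(low)) {
    target[low] <- P_command[low] +
      noise$eom_quad * (P_command[low] - noise$eom_quad_threshold)^2
  }
  if (noise$eom_tau <= 0) {
    target
  } else {
    target + (P_prev_actual - target) * exp(-dt / noise$eom_tau)
  }
}

#' Measure the illumination power
#'
#' Photodiode measurement of the actual power: additive Gaussian noise of SD
#' `pd_sigma` (normalized power units), then digitization at the power-DAC
#' gain \eqn{G_P = P_{max}/2^{B_P}}.  The code is floored at 1 LSB so the
#' downstream log2 encoding is always defined.
#'
#' @param P_actual Actual power (>= 0); vectorized.
#' @param cfg An [acquisition_config()].
#' @param noise A [noise_model()].
#' @return Integer codes in `[1, 2^B_P]`.
#' @examples
#' cfg <- acquisition_config()
#' measure_power(1, cfg, noise_model(pd_sigma = 0))     # 16384
#' measure_power(0.5, cfg, noise_model(pd_sigma = 0))   # 8192
#' @export
measure_power <- function(P_actual, cfg, noise = noise_model()) {
  if (any(P_actual < 0)) stop("`P_actual` must be >= 0", call. = FALSE)
  eps <- if (noise$pd_sigma > 0) {
    stats::rnorm(length(P_actual), 0, noise$pd_sigma)
  } else 0
  code <- round((P_actual + eps) / cfg$G_P)
  pmin(pmax(code, 1), cfg$P_max_code)
}
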