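#' Ornstein-Uhlenbeck modulation of the external input rate
#'
#' Makes the external EPSP rate `I_re` a noisy variable: each step,
#' `I_re <- I_re + (mu_noise - I_re) / tau_noise * dt + k_noise * sqrt(dt) * g`
#' with `g ~ N(0, 1)` (Euler-Maruyama), clamped at 0 because Poisson rates
#' cannot be negative. The process is initialised at `mu_noise`.
#'
#' The noise amplitude is specified either relative to the mean
#' (`amp_mode = "relative"`, default: `k_noise = amp * mu_noise`) or as an
#' absolute value in Hz (`amp_mode = "absolute"`); in both cases `k_noise`
#' is in Hz per square-root second. The stationary standard deviation of
#' the unclamped process is `k_noise * sqrt(tau_noise / 2)`.
#'
#' @param mu_noise Mean rate (Hz).
#' @param tau_noise Decay time constant (s).
#' @param amp Noise amplitude (see `amp_mode`).
#' @param amp_mode `"relative"` (fraction of `mu_noise`) or `"absolute"`
#'   (Hz per sqrt(s)).
#' @return An `ou_params` object with fields `mu_noise`, `tau_noise` (s) and
#'   `k_noise` (Hz per sqrt(s)).
#' @export
ou_params <- function(mu_noise = 100, tau_noise = 120, amp = 0.05,
                      amp_mode = c("relative", "absolute")) {
  amp_mode <- match.arg(amp_mode)
  if (tau_noise <= 0) stop("tau_noise must be positive")
  if (amp < 0) stop("noise amplitude must be >= 0")
  k_noise <- if (amp_mode == "relative") amp * mu_noise else amp
  structure(list(mu_noise = mu_noise, tau_noise = tau_noise,
                 k_noise = k_noise),
            class = "ou_params")
}

#' Advance the noisy input rate by one step
#'
#' Reference R implementation of the Euler-Maruyama update used inside the
#' simulation core.
#'
#' @param I_re Current rate (Hz).
#' @param params An [ou_params()] object.
#' @param dt_s Step size in seconds.
#' @param g Optional standard-normal innovation; drawn if missing.
#' @return Updated rate (Hz), clamped at 0.
#' @export
ou_step <- function(I_re, params, dt_s, g = rnorm(1)) {
  stopifnot(inherits(params, "ou_params"))
  out <- I_re + (params$mu_noise - I_re) / params$tau_noise * dt_s +
    params$k_noise * sqrt(dt_s) * g
  max(out, 0)
}

#' Simulate a path of the noisy input rate
#'
#' @param params An [ou_params()] object.
#' @param duration_s Path length (s).
#' @param dt_s Step size (s).
#' @param seed Integer seed.
#' @return Numeric vector of rates (Hz), starting from `mu_noise`.
#' @export
ou_path <- function(params, duration_s, dt_s = 0.001, seed = 1) {
  stopifnot(inherits(params, "ou_params"))
  n <- floor(duration_s / dt_s)
  local_seed(seed, {
    g <- rnorm(n)
    out <- numeric(n + 1)
    out[1] <- params$mu_noise
    for (i in seq_len(n)) out[i + 1] <- ou_step(out[i], params, dt_s, g[i])
    out
  })
}
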