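#' Single-neuron model parameters
#'
#' Parameters of the modified integrate-and-fire neuron. The membrane
#' potential is `V = V_rest + V_syn - HAP - AHP + DAP`, where `V_syn`
#' integrates synaptic input with half-life `lambda_syn` and the three
#' post-spike potentials are incremented by their `k` amplitude at each spike
#' and decay exponentially with their own half-lives, accumulating across
#' intervals (no post-spike reset). External drive is a pair of Poisson
#' streams: EPSPs of amplitude `e_h` at rate `I_re` and IPSPs of amplitude
#' `i_h` at rate `I_ratio * I_re`.
#'
#' Defaults are the reference single-neuron parameter set used throughout:
#' `I_re` 300 Hz, `I_ratio` 1, `e_h` 3 mV, `i_h` -3 mV, `lambda_syn` 7.5 ms,
#' `k_HAP` 30 mV, `lambda_HAP` 8 ms, AHP and DAP amplitudes 0 (half-lives
#' 500 and 1000 ms), `V_rest` -62 mV, `V_thresh` -50 mV, 2-ms absolute
#' refractory period, 1-ms time step.
#'
#' @param I_re External EPSP rate (Hz).
#' @param I_ratio IPSP/EPSP rate ratio (dimensionless).
#' @param e_h,i_h EPSP and IPSP amplitudes (mV); `i_h <= 0 <= e_h`.
#' @param lambda_syn PSP half-life (ms).
#' @param k_HAP,lambda_HAP HAP per-spike amplitude (mV) and half-life (ms).
#' @param k_AHP,lambda_AHP AHP amplitude (mV) and half-life (ms).
#' @param k_DAP,lambda_DAP DAP amplitude (mV) and half-life (ms).
#' @param V_rest,V_thresh Resting and threshold potentials (mV).
#' @param t_refabs Absolute refractory period (ms).
#' @param dt Simulation time step (ms); 1 ms default, usable down to 0.1 ms.
#' @return A `neuron_params` object (named list).
#' @export
neuron_params <- function(I_re = 300, I_ratio = 1, e_h = 3, i_h = -3,
                          lambda_syn = 7.5, k_HAP = 30, lambda_HAP = 8,
                          k_AHP = 0, lambda_AHP = 500, k_DAP = 0,
                          lambda_DAP = 1000, V_rest = -62, V_thresh = -50,
                          t_refabs = 2, dt = 1) {
  p <- list(I_re = I_re, I_ratio = I_ratio, e_h = e_h, i_h = i_h,
            lambda_syn = lambda_syn, k_HAP = k_HAP, lambda_HAP = lambda_HAP,
            k_AHP = k_AHP, lambda_AHP = lambda_AHP, k_DAP = k_DAP,
            lambda_DAP = lambda_DAP, V_rest = V_rest, V_thresh = V_thresh,
            t_refabs = t_refabs, dt = dt)
  validate_neuron_params(p)
  structure(p, class = "neuron_params")
}

validate_neuron_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite number")
  }
  if (p$I_re < 0 || p$I_ratio < 0) stop("input rates must be non-negative")
  for (nm in c("lambda_syn", "lambda_HAP", "lambda_AHP", "lambda_DAP")) {
    if (p[[nm]] <= 0) stop("half-life '", nm, "' must be positive")
  }
  if (p$k_HAP < 0 || p$k_AHP < 0) stop("k_HAP and k_AHP must be >= 0")
  if (p$i_h > 0 || p$e_h < 0) stop("require i_h <= 0 <= e_h")
  if (p$dt <= 0) stop("dt must be positive")
  if (p$t_refabs < 0) stop("t_refabs must be >= 0")
  invisible(p)
}

#' Convert an exponential half-life to a decay time constant
#'
#' `tau = lambda / ln(2)`, so decay by `exp(-t/tau)` halves a quantity after
#' exactly `lambda` ms.
#'
#' @param lambda_x Half-life (ms), positive.
#' @return Time constant (ms).
#' @examples
#' half_life_to_tau(7.5) # 10.82 ms, the default PSP time constant
#' @export
half_life_to_tau <- function(lambda_x) {
  if (!is.numeric(lambda_x) || any(!is.finite(lambda_x)) || any(lambda_x <= 0)) {
    stop("half-life must be a positive finite number")
  }
  lambda_x / log(2)
}

#' Draw one step of external synaptic input
#'
#' EPSP and IPSP counts for one time step are drawn from independent Poisson
#' distributions with means `I_re * dt / 1000` and `I_ratio * I_re * dt /
#' 1000`, and summed with their amplitudes: `I_ext = e_h * e_n + i_h * i_n`.
#' This is the reference R implementation of the external drive; the
#' simulation loop draws the same quantities internally per neuron.
#'
#' @param params A [neuron_params()] object.
#' @param n Number of steps to draw.
#' @return Numeric vector of `n` input increments (mV).
#' @export
external_input_step <- function(params, n = 1) {
  stopifnot(inherits(params, "neuron_params"))
  lam_e <- params$I_re * params$dt / 1000
  lam_i <- params$I_ratio * params$I_re * params$dt / 1000
  params$e_h * rpois(n, lam_e) + params$i_h * rpois(n, lam_i)
}

#' Simulate a single neuron
#'
#' Runs the modified integrate-and-fire model forward for `duration_ms`.
#' Each step: decay `V_syn`, HAP, AHP and DAP by their exact exponential
#' factors, add the step's Poisson input to `V_syn`, compute
#' `V = V_rest + V_syn - HAP - AHP + DAP`, and fire a spike when
#' `V >= V_thresh` and the absolute refractory period has elapsed. Post-spike
#' increments take effect from the next step. Identical `(params,
#' duration_ms, seed)` give identical output.
#'
#' @param params A [neuron_params()] object.
#' @param duration_ms Simulated time (ms), at least one step.
#' @param seed Integer seed for the neuron's private RNG stream.
#' @param record_v If `TRUE`, also return the membrane potential at every
#'   step (needed for spike-triggered averages).
#' @param stream_id Sub-stream identifier; neuron `i` of a network uses
#'   stream `i - 1`, so a single run with `stream_id = i - 1` reproduces that
#'   neuron's external input exactly.
#' @param init_at_k If `TRUE` (default, matching the model definition) the
#'   post-spike potentials start at their `k` amplitudes; `FALSE` starts them
#'   at 0 for steady-state analyses.
#' @param ou Optional [ou_params()] making `I_re` a noisy variable.
#' @param perturbations Optional data frame with columns `onset_ms`,
#'   `dur_ms`, `delta_hz`: step changes added to the external input rate.
#' @param integration Per-step decay factor: `"euler"` (default,
#'   `1 - dt/tau`, the direct discretisation of the model equations) or
#'   `"exact"` (`exp(-dt/tau)`, half-lives independent of `dt`).
#' @return A [spike_train()]; with `record_v = TRUE`, attribute `v` holds the
#'   voltage trace (mV, one value per step) and attribute `dt` its sampling
#'   step.
#' @examples
#' st <- simulate_single(neuron_params(), duration_ms = 10000, seed = 1)
#' mean_rate(st)
#' @export
simulate_single <- function(params, duration_ms, seed = 1, record_v = FALSE,
                            stream_id = 0, init_at_k = TRUE, ou = NULL,
                            perturbations = NULL, integration = "euler") {
  stopifnot(inherits(params, "neuron_params"))
  if (duration_ms < params$dt) stop("duration must be at least one time step")
  res <- simulate_network_raw(
    pm = neuron_param_matrix(list(params), synweight = 1),
    edges = empty_connectivity(), syntrans = 0.5, n_h = 3, dt = params$dt,
    duration_ms = duration_ms, seed = seed, stream_ids = stream_id,
    record_idx = if (record_v) 0L else integer(0), init_at_k = init_at_k,
    ou = ou, perturbations = perturbations, integration = integration)
  st <- spike_train(res$spikes[[1]], duration = duration_ms)
  if (record_v) {
    attr(st, "v") <- as.numeric(res$v[, 1])
    attr(st, "dt") <- params$dt
  }
  st
}

# Assemble the per-neuron parameter matrix consumed by the C++ core.
neuron_param_matrix <- function(param_list, synweight) {
  cols <- c("I_re", "I_ratio", "e_h", "i_h", "lambda_syn", "k_HAP",
            "lambda_HAP", "k_AHP", "lambda_AHP", "k_DAP", "lambda_DAP",
            "V_rest", "V_thresh", "t_refabs")
  pm <- t(vapply(param_list, function(p) unlist(p[cols]), numeric(length(cols))))
  cbind(pm, synweight = rep_len(synweight, length(param_list)))
}

#' Relative refractory period implied by the post-spike potentials
#'
#' The time for the membrane potential to return to within 1 mV of rest
#' after a spike, in the absence of any synaptic input. Computed from the
#' closed-form deterministic decay of the post-spike potentials (evaluated
#' on a fine time grid, since the HAP/AHP/DAP mixture need not be monotone);
#' for an HAP-only neuron this equals `lambda_HAP * log2(k_HAP / 1 mV)`.
#'
#' @param params A [neuron_params()] object.
#' @param tol_mv Return threshold (mV), default 1.
#' @param grid_dt Time grid resolution (ms), default 0.01.
#' @param t_max Search horizon (ms), default 20000.
#' @return Duration in ms (0 if the deviation never exceeds `tol_mv`).
#' @examples
#' relative_refractory_estimate(neuron_params(k_HAP = 30, lambda_HAP = 8))
#' @export
relative_refractory_estimate <- function(params, tol_mv = 1, grid_dt = 0.01,
                                         t_max = 2e4) {
  stopifnot(inherits(params, "neuron_params"))
  if (params$k_HAP == 0 && params$k_AHP == 0 && params$k_DAP == 0) return(0)
  tt <- seq(0, t_max, by = grid_dt)
  dev <- -params$k_HAP * 2^(-tt / params$lambda_HAP) -
    params$k_AHP * 2^(-tt / params$lambda_AHP) +
    params$k_DAP * 2^(-tt / params$lambda_DAP)
  inside <- abs(dev) <= tol_mv
  first_in <- which(inside)[1]
  if (is.na(first_in)) {
    stop("membrane potential does not return within tolerance by t_max")
  }
  tt[first_in]
}
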