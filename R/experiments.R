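#' Reference parameter presets
#'
#' Named parameter sets for the standard in-silico experiments:
#' * `"single"` - the default single neuron ([neuron_params()]).
#' * `"net_slow"` / `"net_fast"` - 50-neuron single-type networks of 'slow
#'   HAP' (`k_HAP` 20 mV, `lambda_HAP` 40 ms) or 'fast HAP' (`k_HAP` 40 mV,
#'   `lambda_HAP` 10 ms) cells, `I_re` 200 Hz, `I_ratio` 0.5, connection
#'   probability 0.5, transmission probability 0.5, delays 5-15 ms.
#' * `"signal_generator"` - 100 slow-HAP neurons with `esyn_1` 0.35
#'   (equivalent to 0.7 in a 50-neuron network).
#' * `"two_type"` - 100 interconnected slow-HAP neurons (`k_HAP` 60,
#'   `lambda_HAP` 50 ms, `I_re` 180 Hz, `esyn_1` 0.35) projecting with
#'   probability 0.2 onto 100 fast-HAP neurons (`k_HAP` 60, `lambda_HAP`
#'   5 ms, `I_re` 80 Hz); delay range widened to 15 ms.
#' * `"bistable"` - 100 slow-HAP neurons (`k_HAP` 30, `lambda_HAP` 40 ms)
#'   each with a DAP (`k_DAP` 0.75 mV, `lambda_DAP` 750 ms), `esyn_1` 0.25,
#'   `I_re` 100 Hz.
#'
#' @param name Preset name.
#' @return A [neuron_params()] (for `"single"`) or [network_params()`]
#'   object.
#' @export
preset_params <- function(name = c("single", "net_slow", "net_fast",
                                   "signal_generator", "two_type",
                                   "bistable")) {
  name <- match.arg(name)
  slow <- neuron_params(I_re = 200, I_ratio = 0.5, k_HAP = 20,
                        lambda_HAP = 40)
  switch(name,
    single = neuron_params(),
    net_slow = network_params(vmn1 = 50, esyn_1 = 0.5, type1 = slow),
    net_fast = network_params(vmn1 = 50, esyn_1 = 0.5,
                              type1 = neuron_params(I_re = 200,
                                                    I_ratio = 0.5,
                                                    k_HAP = 40,
                                                    lambda_HAP = 10)),
    signal_generator = network_params(vmn1 = 100, esyn_1 = 0.35,
                                      type1 = slow),
    two_type = network_params(
      vmn1 = 100, vmn2 = 100, esyn_1 = 0.35, esyn_12 = 0.2,
      delta_range = 15,
      type1 = neuron_params(I_re = 180, I_ratio = 0.5, k_HAP = 60,
                            lambda_HAP = 50),
      type2 = neuron_params(I_re = 80, I_ratio = 0.5, k_HAP = 60,
                            lambda_HAP = 5)),
    bistable = network_params(
      vmn1 = 100, esyn_1 = 0.25,
      type1 = neuron_params(I_re = 100, I_ratio = 0.5, k_HAP = 30,
                            lambda_HAP = 40, k_DAP = 0.75,
                            lambda_DAP = 750)))
}

set_type1 <- function(np, ...) {
  over <- list(...)
  p <- np$type1
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  np$type1 <- do.call(neuron_params, unclass(p))
  np
}

#' Connection-density sweep of a single-type network
#'
#' Simulates the 50-neuron network at each connection probability and
#' summarises one exemplar neuron plus the population. As `esyn_1`
#' increases in a slow-HAP network the firing rate rises and the ISI
#' distribution develops a second (short-interval, burst) mode.
#'
#' @param esyn_values Connection probabilities to sweep.
#' @param params Base [network_params()] (default the slow-HAP preset).
#' @param duration_s Run length per point (s).
#' @param seed Integer seed.
#' @return List of per-`esyn` results: `esyn`, `mean_rate` (spikes/s over
#'   all neurons), `summary` (exemplar [pattern_summary()]), `pop_counts`
#'   (1-ms summed counts).
#' @export
exp_connectivity_sweep <- function(esyn_values = c(0.1, 0.3, 0.5, 0.7),
                                   params = preset_params("net_slow"),
                                   duration_s = 500, seed = 1) {
  lapply(esyn_values, function(es) {
    np <- params
    np$esyn_1 <- es
    res <- simulate_network(np, duration_ms = duration_s * 1000, seed = seed)
    rates <- vapply(res$trains, mean_rate, numeric(1))
    exemplar <- res$trains[[1]]
    sm <- if (length(exemplar$times) >= 100) pattern_summary(exemplar) else NULL
    list(esyn = es, mean_rate = mean(rates), rates = rates, summary = sm,
         pop_counts = population_rate(res$trains, 1))
  })
}

#' Signal-generator experiment: oscillation frequency vs input rate
#'
#' The 100-neuron slow-HAP network with `esyn_1 = 0.35` turns random
#' synaptic input into a rhythmic population signal; the dominant frequency
#' grows with the external input rate (about 2.3 Hz at 130 Hz input to
#' about 6 Hz at 600 Hz).
#'
#' @param i_re_values External input rates to test (Hz).
#' @param params Base [network_params()].
#' @param duration_s Run length per point (s).
#' @param seed Integer seed.
#' @return Data frame with `I_re`, `frequency` (Hz), `significant`,
#'   `mean_rate`.
#' @export
exp_signal_generator <- function(i_re_values = c(100, 130, 200, 300, 400,
                                                 600),
                                 params = preset_params("signal_generator"),
                                 duration_s = 500, seed = 1) {
  rows <- lapply(i_re_values, function(ire) {
    np <- set_type1(params, I_re = ire)
    res <- simulate_network(np, duration_ms = duration_s * 1000, seed = seed)
    pc <- population_rate(res$trains, 1)
    of <- oscillation_frequency(pc)
    data.frame(I_re = ire, frequency = of$frequency,
               significant = of$significant,
               mean_rate = mean(vapply(res$trains, mean_rate, numeric(1))))
  })
  do.call(rbind, rows)
}

#' Bistable-network experiment
#'
#' The slow-HAP + DAP network holds a stable slow (~0.85 spikes/s) state at
#' `I_re = 100` Hz and a stable fast (~6 spikes/s) state at `I_re = 110`;
#' transient input perturbations or a noisy input rate switch it between
#' the two. Bistability needs both the DAP and the excitatory connections.
#'
#' @param i_re External input rate (Hz).
#' @param duration_s Run length (s).
#' @param seed Integer seed.
#' @param params Base [network_params()] (default the bistable preset).
#' @param ou Optional [ou_params()] for a noisy input rate.
#' @param perturbations Optional data frame (`onset_ms`, `dur_ms`,
#'   `delta_hz`).
#' @return List with `trains`, `pop_counts` (1-ms bins), `states`
#'   ([segment_bistable_states()] on the run), `params`.
#' @export
exp_bistable <- function(i_re = 100, duration_s = 500, seed = 1,
                         params = preset_params("bistable"), ou = NULL,
                         perturbations = NULL) {
  np <- set_type1(params, I_re = i_re)
  res <- simulate_network(np, duration_ms = duration_s * 1000, seed = seed,
                          ou = ou, perturbations = perturbations)
  pc <- population_rate(res$trains, 1)
  list(trains = res$trains, pop_counts = pc,
       states = segment_bistable_states(pc, n_neurons = np$vmn1),
       params = np)
}

#' Randomly heterogeneous slow-HAP network
#'
#' A network of type-1 neurons with three parameters drawn per neuron from
#' normal distributions: `lambda_HAP ~ N(40, 20)` ms, `I_re ~ N(150, 45)`
#' Hz, and inbound connection probability `esyn_1 ~ N(0.12, 0.15)`.
#' Neurons drawing `esyn_1 <= 0` receive no network connections but still
#' project. Draws of `lambda_HAP` below 2 ms are clamped to 2 ms and
#' negative `I_re` to 0 (physiological bounds). One run reproduces the
#' spread of VMN ISI phenotypes, from silent cells to unimodal and
#' multimodal distributions.
#'
#' @param n Number of neurons.
#' @param duration_s Run length (s).
#' @param seed Integer seed (drives both the parameter draws and the run).
#' @param params Base [network_params()] for non-varied settings.
#' @return List with `trains`, `hetero` (the per-neuron draws), `silent`
#'   (indices of cells with < 2 spikes), `histograms` (5-ms
#'   [isi_histogram()] per non-silent neuron, `NULL` for silent ones).
#' @export
exp_heterogeneous <- function(n = 200, duration_s = 2000, seed = 1,
                              params = preset_params("net_slow")) {
  np <- params
  np$vmn1 <- as.integer(n)
  draws <- local_seed(seed + 211, {
    data.frame(lambda_HAP = pmax(2, rnorm(n, 40, 20)),
               I_re = pmax(0, rnorm(n, 150, 45)),
               esyn = rnorm(n, 0.12, 0.15))
  })
  conn <- build_network(np, seed = seed, esyn_in = draws$esyn)
  res <- simulate_network(np, duration_ms = duration_s * 1000, seed = seed,
                          connectivity = conn,
                          hetero = draws[, c("lambda_HAP", "I_re")])
  silent <- which(vapply(res$trains, function(tr) length(tr$times) < 2,
                         logical(1)))
  hists <- lapply(res$trains, function(tr) {
    if (length(tr$times) < 2) NULL else isi_histogram(tr, 5)
  })
  list(trains = res$trains, hetero = draws, silent = silent,
       histograms = hists, connectivity = conn)
}

#' Run a named experiment from a specification list
#'
#' Config-driven dispatcher used by the command line: `name` selects the
#' experiment and the remaining entries override its arguments.
#'
#' @param spec List with `name` (one of `"connectivity_sweep"`,
#'   `"signal_generator"`, `"bistable"`, `"heterogeneous"`) plus arguments
#'   of the corresponding `exp_*` function.
#' @return The experiment's result.
#' @export
run_experiment <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$name))
  fn <- switch(spec$name,
               connectivity_sweep = exp_connectivity_sweep,
               signal_generator = exp_signal_generator,
               bistable = exp_bistable,
               heterogeneous = exp_heterogeneous,
               stop("unknown experiment: ", spec$name))
  do.call(fn, spec[setdiff(names(spec), "name")])
}
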