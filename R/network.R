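#' Network model parameters
#'
#' A population of type-1 neurons (optionally plus a receiving type-2
#' population) connected at random by excitatory synapses. Each ordered pair
#' of type-1 neurons is connected with probability `esyn_1`; each type-1
#' neuron connects to each type-2 neuron with probability `esyn_12`; type-2
#' neurons are not interconnected and do not project back. A presynaptic
#' spike is transmitted with probability `syntrans` and, when successful,
#' delivers one network EPSP of amplitude `synweight_1 * n_h` mV after a
#' per-connection delay `delta_min + delta_range * U(0,1)` ms.
#'
#' Defaults are the reference single-cell-type network settings: 50 neurons,
#' `I_re` 200 Hz, `I_ratio` 0.5, connection probability 0.5, transmission
#' probability 0.5, delays 5-15 ms, network EPSP 3 mV with 7.5-ms half-life.
#'
#' @param vmn1 Number of type-1 neurons.
#' @param vmn2 Number of type-2 neurons (0 for a single-type network).
#' @param esyn_1 Type-1 to type-1 connection probability.
#' @param esyn_12 Type-1 to type-2 connection probability.
#' @param synweight_1 Multiplier applied to network PSP amplitudes.
#' @param syntrans Per-spike transmission success probability.
#' @param delta_min,delta_range Transmission delay: fixed base plus uniform
#'   random component (ms). `delta_min + delta_range` must fit inside the
#'   20-ms input-queue horizon.
#' @param n_h Network EPSP amplitude (mV); decays with the neuron's
#'   `lambda_syn`.
#' @param type1,type2 [neuron_params()] for each population. Type-1 defaults
#'   to a 'slow HAP' cell (`k_HAP` 20 mV, `lambda_HAP` 40 ms).
#' @return A `network_params` object.
#' @export
network_params <- function(vmn1 = 50, vmn2 = 0, esyn_1 = 0.5, esyn_12 = 0,
                           synweight_1 = 1, syntrans = 0.5, delta_min = 5,
                           delta_range = 10, n_h = 3,
                           type1 = neuron_params(I_re = 200, I_ratio = 0.5,
                                                 k_HAP = 20, lambda_HAP = 40),
                           type2 = NULL) {
  if (vmn1 < 1) stop("need at least one type-1 neuron")
  if (vmn2 > 0 && is.null(type2)) stop("type2 parameters required when vmn2 > 0")
  for (p in c(esyn_1, esyn_12, syntrans)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  if (delta_min < 0 || delta_range < 0) stop("delays must be non-negative")
  if (delta_min + delta_range > 20) {
    stop("delta_min + delta_range exceeds the 20-ms input queue horizon")
  }
  stopifnot(inherits(type1, "neuron_params"),
            is.null(type2) || inherits(type2, "neuron_params"))
  structure(list(vmn1 = as.integer(vmn1), vmn2 = as.integer(vmn2),
                 esyn_1 = esyn_1, esyn_12 = esyn_12,
                 synweight_1 = synweight_1, syntrans = syntrans,
                 delta_min = delta_min, delta_range = delta_range, n_h = n_h,
                 type1 = type1, type2 = type2),
            class = "network_params")
}

empty_connectivity <- function() {
  structure(data.frame(src = integer(0), tgt = integer(0),
                       delay_ms = numeric(0)),
            class = c("connectivity", "data.frame"))
}

#' Build the random directed connectivity of a network
#'
#' Connections are static and generated before the run: each eligible
#' ordered pair is an independent Bernoulli draw (self-connections excluded;
#' the two directions of a pair are independent), and each edge gets a
#' delay `delta_min + delta_range * U(0,1)`, frozen at build time.
#'
#' @param params A [network_params()] object.
#' @param seed Integer seed (the build uses its own RNG state and restores
#'   R's).
#' @param esyn_in Optional per-neuron inbound connection probability for
#'   type-1 neurons (length `vmn1`), used by heterogeneous networks; values
#'   `<= 0` mean the neuron receives no network connections but still
#'   projects.
#' @return A `connectivity` data frame with columns `src`, `tgt` (1-based
#'   neuron indices; type-2 neurons follow type-1) and `delay_ms`.
#' @export
build_network <- function(params, seed = 1, esyn_in = NULL) {
  stopifnot(inherits(params, "network_params"))
  n1 <- params$vmn1
  n2 <- params$vmn2
  if (is.null(esyn_in)) {
    esyn_in <- rep(params$esyn_1, n1)
  } else {
    stopifnot(length(esyn_in) == n1)
  }
  edges <- local_seed(seed, {
    src <- integer(0); tgt <- integer(0)
    # type1 -> type1, inbound probability owned by the target neuron
    for (j in seq_len(n1)) {
      pj <- esyn_in[j]
      if (pj <= 0) next
      cand <- setdiff(seq_len(n1), j)
      sel <- cand[runif(length(cand)) < pj]
      src <- c(src, sel); tgt <- c(tgt, rep(j, length(sel)))
    }
    # type1 -> type2
    if (n2 > 0 && params$esyn_12 > 0) {
      for (j in seq_len(n2)) {
        sel <- which(runif(n1) < params$esyn_12)
        src <- c(src, sel); tgt <- c(tgt, rep(n1 + j, length(sel)))
      }
    }
    delay <- params$delta_min + params$delta_range * runif(length(src))
    data.frame(src = src, tgt = tgt, delay_ms = delay)
  })
  edges <- edges[order(edges$src, edges$tgt), , drop = FALSE]
  rownames(edges) <- NULL
  class(edges) <- c("connectivity", "data.frame")
  edges
}

# Evaluate expr with a private R RNG state seeded by `seed`.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Shared low-level wrapper around the C++ core.
simulate_network_raw <- function(pm, edges, syntrans, n_h, dt, duration_ms,
                                 seed, stream_ids, record_idx, init_at_k,
                                 ou = NULL, perturbations = NULL,
                                 integration = "euler") {
  n_steps <- as.integer(floor(duration_ms / dt))
  delay_steps <- pmax(1L, as.integer(round(edges$delay_ms / dt)))
  ou_spec <- if (is.null(ou)) {
    list(use = FALSE, mu = 0, tau_ms = 1, k_per_sqrt_ms = 0)
  } else {
    stopifnot(inherits(ou, "ou_params"))
    list(use = TRUE, mu = ou$mu_noise, tau_ms = ou$tau_noise * 1000,
         k_per_sqrt_ms = ou$k_noise / sqrt(1000))
  }
  pert <- if (is.null(perturbations)) {
    matrix(numeric(0), 0, 3)
  } else {
    as.matrix(perturbations[, c("onset_ms", "dur_ms", "delta_hz")])
  }
  integration <- match.arg(integration, c("euler", "exact"))
  sim_network_cpp(pm, as.integer(edges$src - 1L), as.integer(edges$tgt - 1L),
                  delay_steps, syntrans, n_h, dt, n_steps, as.integer(seed),
                  as.integer(stream_ids), as.integer(record_idx),
                  init_at_k, ou_spec, pert, !is.null(ou),
                  integration == "euler")
}

#' Simulate a network of modified integrate-and-fire neurons
#'
#' Runs synchronous per-step updates of all neurons. Each neuron draws its
#' external Poisson input from its own RNG stream; network EPSPs from spikes
#' at step `t` are delivered (subject to a Bernoulli `syntrans` trial per
#' connection, drawn from the receiving neuron's transmission stream) at
#' step `t + delay`.
#'
#' @param params A [network_params()] object.
#' @param duration_ms Simulated time (ms).
#' @param seed Integer seed; together with `params` and the connectivity it
#'   fully determines the output.
#' @param connectivity Optional prebuilt [build_network()] result; built
#'   from `seed` if missing.
#' @param record_v Integer vector of neuron indices (1-based) whose membrane
#'   potential should be recorded.
#' @param hetero Optional data frame of per-neuron type-1 parameter
#'   overrides; columns named after [neuron_params()] fields (e.g.
#'   `lambda_HAP`, `I_re`), one row per type-1 neuron.
#' @param ou Optional [ou_params()]: the external input rate becomes a
#'   shared Ornstein-Uhlenbeck variable for all neurons.
#' @param perturbations Optional data frame (`onset_ms`, `dur_ms`,
#'   `delta_hz`) of transient changes to the external input rate.
#' @param init_at_k Start post-spike potentials at their `k` values
#'   (default) or at 0.
#' @param integration `"euler"` (default) or `"exact"` per-step decay; see
#'   [simulate_single()].
#' @return List with `trains` (list of [spike_train()], type-2 neurons after
#'   type-1), `v` (matrix of recorded voltages, one column per recorded
#'   neuron), `rate` (the OU rate path if `ou` was given), `connectivity`,
#'   and `diag` (transmission attempt/delivery counts).
#' @export
simulate_network <- function(params, duration_ms, seed = 1,
                             connectivity = NULL, record_v = integer(0),
                             hetero = NULL, ou = NULL, perturbations = NULL,
                             init_at_k = TRUE, integration = "euler") {
  stopifnot(inherits(params, "network_params"))
  n1 <- params$vmn1
  n <- n1 + params$vmn2
  plist <- c(rep(list(params$type1), n1),
             rep(list(params$type2), params$vmn2))
  if (!is.null(hetero)) {
    stopifnot(is.data.frame(hetero), nrow(hetero) == n1)
    for (i in seq_len(n1)) {
      p <- plist[[i]]
      for (nm in names(hetero)) p[[nm]] <- hetero[[nm]][i]
      validate_neuron_params(p)
      plist[[i]] <- p
    }
  }
  if (is.null(connectivity)) {
    connectivity <- build_network(params, seed = seed)
  }
  if (nrow(connectivity) > 0 &&
      (min(connectivity$src) < 1 || max(connectivity$tgt) > n)) {
    stop("connectivity indices outside the population")
  }
  dt <- params$type1$dt
  res <- simulate_network_raw(
    pm = neuron_param_matrix(plist, synweight = params$synweight_1),
    edges = connectivity, syntrans = params$syntrans, n_h = params$n_h,
    dt = dt, duration_ms = duration_ms, seed = seed,
    stream_ids = seq_len(n) - 1L, record_idx = as.integer(record_v) - 1L,
    init_at_k = init_at_k, ou = ou, perturbations = perturbations,
    integration = integration)
  trains <- lapply(res$spikes, spike_train, duration = duration_ms)
  list(trains = trains, v = res$v, rate = res$rate,
       connectivity = connectivity, diag = res$diag)
}

#' Write / read a connectivity edge list
#'
#' Plain-text tab-separated `src`, `tgt`, `delay_ms` columns, for exact
#' reproduction of a network realisation.
#'
#' @param connectivity A [build_network()] result.
#' @param path File path.
#' @export
write_connectivity <- function(connectivity, path) {
  write.table(as.data.frame(connectivity), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("src", "tgt", "delay_ms") %in% names(df)))
  class(df) <- c("connectivity", "data.frame")
  df
}
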