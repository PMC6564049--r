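#' Physiological ranges of the fitted single-neuron parameters
#'
#' The search box used by the genetic algorithm: `I_re` 100-2000 Hz,
#' `k_HAP` 0-100 mV, `lambda_HAP` 2-100 ms, `k_AHP` 0-5 mV, `lambda_AHP`
#' 50-1500 ms, `k_DAP` 0-10 mV, `lambda_DAP` 20-2000 ms.
#'
#' @return Matrix with rows `min`/`max`, one column per parameter.
#' @export
fit_param_ranges <- function() {
  rbind(min = c(I_re = 100, k_HAP = 0, lambda_HAP = 2, k_AHP = 0,
                lambda_AHP = 50, k_DAP = 0, lambda_DAP = 20),
        max = c(I_re = 2000, k_HAP = 100, lambda_HAP = 100, k_AHP = 5,
                lambda_AHP = 1500, k_DAP = 10, lambda_DAP = 2000))
}

mode_param_names <- function(mode) {
  switch(mode,
         "HAP" = c("I_re", "k_HAP", "lambda_HAP"),
         "HAP+AHP" = c("I_re", "k_HAP", "lambda_HAP", "k_AHP", "lambda_AHP"),
         "HAP+DAP" = c("I_re", "k_HAP", "lambda_HAP", "k_DAP", "lambda_DAP"),
         stop("unknown fitting mode: ", mode))
}

#' Genetic-algorithm and fit-measure configuration
#'
#' Defaults follow the reference protocol: candidates are simulated for
#' 1000 s, populations of 128 evolve for 40 generations with 32 parents and
#' per-parameter mutation probability 0.05; the fit score weights the ISI
#' head range (5-ms bin indices 0-50, i.e. 0-250 ms) by 200 and the ISI
#' tail range (bins 50-200, 250-1000 ms), hazard, and IoD range by 100
#' each.
#'
#' @param run_time_s Simulated seconds per candidate evaluation.
#' @param pop_size Candidates per generation.
#' @param parents Number of top-ranked candidates bred each generation.
#' @param generations Number of generations.
#' @param mut_prob Per-parameter mutation probability.
#' @param w_head,w_tail,w_hazard,w_iod Fit-measure weights.
#' @param head_start,head_stop,tail_start,tail_stop ISI range bounds, in
#'   5-ms bin indices.
#' @param isi_binwidth ISI bin width (ms).
#' @param discard_ms Initial transient discarded from candidate runs (ms).
#' @return A `ga_config` object.
#' @export
ga_config <- function(run_time_s = 1000, pop_size = 128, parents = 32,
                      generations = 40, mut_prob = 0.05, w_head = 200,
                      w_tail = 100, w_hazard = 100, w_iod = 100,
                      head_start = 0, head_stop = 50, tail_start = 50,
                      tail_stop = 200, isi_binwidth = 5, discard_ms = 5000) {
  if (parents > pop_size) stop("parents must not exceed population size")
  if (any(c(w_head, w_tail, w_hazard, w_iod) < 0)) stop("weights must be >= 0")
  structure(as.list(environment()), class = "ga_config")
}

pad_to <- function(x, n) {
  if (length(x) >= n) x[seq_len(n)] else c(x, rep(0, n - length(x)))
}

#' Weighted fit score between two spike-pattern summaries
#'
#' Each component is the mean absolute per-bin difference over its range:
#' normalised ISI counts over the head and tail bin ranges, hazard values
#' over bins where the target has at least 20 surviving intervals (noisy
#' hazard bins are masked), and the seven IoD-range values. The weighted
#' sum is the single fit score (0 for identical summaries; lower is
#' better).
#'
#' @param model,target [pattern_summary()] objects on identical binnings.
#' @param config A [ga_config()] (weights and ranges).
#' @return The score, with attribute `components` holding the unweighted
#'   component distances.
#' @export
fit_score <- function(model, target, config = ga_config()) {
  stopifnot(inherits(model, "pattern_summary"),
            inherits(target, "pattern_summary"))
  if (model$isi$binwidth != target$isi$binwidth) {
    stop("summaries use different ISI binnings")
  }
  nb <- config$tail_stop
  m_isi <- pad_to(model$isi$norm_counts, nb)
  t_isi <- pad_to(target$isi$norm_counts, nb)
  head_idx <- seq(config$head_start + 1, config$head_stop)
  tail_idx <- seq(config$tail_start + 1, config$tail_stop)
  d_head <- mean(abs(m_isi[head_idx] - t_isi[head_idx]))
  d_tail <- mean(abs(m_isi[tail_idx] - t_isi[tail_idx]))

  m_haz <- pad_to(model$hazard$hazard, nb)
  t_haz <- pad_to(target$hazard$hazard, nb)
  t_surv <- pad_to(target$hazard$survivors, nb)
  ok <- t_surv >= 20 & !is.na(t_haz) & !is.na(m_haz)
  d_haz <- if (any(ok)) mean(abs(m_haz[ok] - t_haz[ok])) else 1

  d_iod <- if (anyNA(model$iod) || anyNA(target$iod)) {
    Inf
  } else {
    mean(abs(model$iod - target$iod))
  }

  comps <- c(head = d_head, tail = d_tail, hazard = d_haz, iod = d_iod)
  score <- config$w_head * d_head + config$w_tail * d_tail +
    config$w_hazard * d_haz + config$w_iod * d_iod
  attr(score, "components") <- comps
  score
}

cand_seed <- function(seed, gen, idx) {
  ((seed %% 100000) * 100003 + gen * 1009 + idx * 7) %% 2147483647
}

# Build full neuron parameters from a candidate vector of a given mode.
candidate_params <- function(cand, mode, base_params) {
  p <- base_params
  p$k_AHP <- 0
  p$k_DAP <- 0
  for (nm in names(cand)) p[[nm]] <- unname(cand[nm])
  validate_neuron_params(p)
  p
}

evaluate_candidate <- function(cand, mode, base_params, config, sim_seed) {
  p <- candidate_params(cand, mode, base_params)
  st <- simulate_single(p, duration_ms = config$run_time_s * 1000,
                        seed = sim_seed)
  if (length(st$times) < 100) {
    return(list(summary = NULL, components = c(head = Inf, tail = Inf,
                                               hazard = Inf, iod = Inf)))
  }
  list(summary = pattern_summary(st, isi_binwidth = config$isi_binwidth,
                                 discard_ms = config$discard_ms))
}

#' Fit the single-neuron model to a target spike pattern with a GA
#'
#' A population of random parameter sets (uniform within
#' [fit_param_ranges()]) is evaluated by simulating each candidate,
#' summarising its output and scoring it against the target with
#' [fit_score()]. Each generation, the top-ranked `parents` candidates are
#' interbred (uniform per-parameter crossover between two distinct random
#' parents), children are mutated (per-parameter redraw within range), and
#' the best candidate is carried over unchanged (elitism), so the
#' best-score trace is non-increasing. Candidate simulations use seeds
#' derived from `(seed, generation, index)` so re-evaluation is
#' bit-identical.
#'
#' @param target A [spike_train()] (at least 500 s and 100 spikes) or a
#'   precomputed [pattern_summary()].
#' @param mode Post-spike potential combination: `"HAP"`, `"HAP+AHP"` or
#'   `"HAP+DAP"`.
#' @param config A [ga_config()].
#' @param seed Integer master seed for the run.
#' @param base_params Fixed (non-fitted) neuron parameters.
#' @param init_pop Optional initial population: matrix with one row per
#'   fitted parameter (rownames matching the mode's parameters) and
#'   `pop_size` columns; random within range when `NULL`.
#' @return A `fit_result`: list with `params` (best candidate, named
#'   vector), `score`, `components`, `trace` (best score per generation),
#'   `mode`.
#' @export
ga_run <- function(target, mode = "HAP", config = ga_config(), seed = 1,
                   base_params = neuron_params(), init_pop = NULL) {
  if (inherits(target, "spike_train")) {
    if (length(target$times) < 100) {
      stop("degenerate fit target: fewer than 100 spikes")
    }
    target <- pattern_summary(target, isi_binwidth = config$isi_binwidth,
                              discard_ms = config$discard_ms)
  }
  stopifnot(inherits(target, "pattern_summary"))
  pn <- mode_param_names(mode)
  rng <- fit_param_ranges()[, pn, drop = FALSE]
  np <- length(pn)

  local_seed(seed, {
    pop <- if (is.null(init_pop)) {
      matrix(runif(np * config$pop_size, rng["min", ], rng["max", ]),
             nrow = np, dimnames = list(pn, NULL))
    } else {
      stopifnot(nrow(init_pop) == np, ncol(init_pop) == config$pop_size,
                all(rownames(init_pop) == pn),
                all(init_pop >= rng["min", ]), all(init_pop <= rng["max", ]))
      init_pop
    }
    scores <- rep(NA_real_, config$pop_size)
    comps <- vector("list", config$pop_size)
    trace <- numeric(config$generations)

    for (gen in seq_len(config$generations)) {
      for (i in seq_len(config$pop_size)) {
        if (!is.na(scores[i])) next  # elite carried with its score
        ev <- evaluate_candidate(pop[, i], mode, base_params, config,
                                 sim_seed = cand_seed(seed, gen, i))
        if (!is.null(ev$summary)) {
          sc <- fit_score(ev$summary, target, config)
          scores[i] <- as.numeric(sc)
          comps[[i]] <- attr(sc, "components")
        } else {
          scores[i] <- Inf
          comps[[i]] <- ev$components
        }
      }
      ord <- order(scores)
      trace[gen] <- scores[ord[1]]
      if (gen == config$generations) break

      parents <- pop[, ord[seq_len(config$parents)], drop = FALSE]
      elite <- pop[, ord[1]]
      elite_score <- scores[ord[1]]
      elite_comp <- comps[[ord[1]]]
      newpop <- matrix(NA_real_, np, config$pop_size,
                       dimnames = list(pn, NULL))
      newpop[, 1] <- elite
      for (i in 2:config$pop_size) {
        pr <- sample.int(ncol(parents), 2)
        mix <- runif(np) < 0.5
        child <- ifelse(mix, parents[, pr[1]], parents[, pr[2]])
        mut <- runif(np) < config$mut_prob
        if (any(mut)) {
          child[mut] <- runif(sum(mut), rng["min", mut], rng["max", mut])
        }
        newpop[, i] <- child
      }
      pop <- newpop
      scores <- rep(NA_real_, config$pop_size)
      comps <- vector("list", config$pop_size)
      scores[1] <- elite_score
      comps[[1]] <- elite_comp
    }

    best <- which.min(scores)
    structure(list(params = pop[, best], score = scores[best],
                   components = comps[[best]], trace = trace, mode = mode,
                   seed = seed),
              class = "fit_result")
  })
}

#' Consensus fit over repeated GA runs
#'
#' Runs [ga_run()] `n_runs` times with distinct seeds and takes the
#' per-parameter median over the `n_best` lowest-scoring runs as the final
#' parameter set (the reference protocol used 100 runs / best 10; the
#' default here is a desk-scale 20 / 5).
#'
#' @inheritParams ga_run
#' @param n_runs Number of independent GA runs.
#' @param n_best Number of best runs entering the median.
#' @return List with `params` (per-parameter medians), `spread`
#'   (per-parameter standard deviation over the best runs), `runs` (all
#'   [ga_run()] results) and `best_idx`.
#' @export
consensus_fit <- function(target, mode = "HAP", config = ga_config(),
                          n_runs = 20, n_best = 5, seed = 1,
                          base_params = neuron_params()) {
  if (n_best > n_runs) stop("n_best must not exceed n_runs")
  if (inherits(target, "spike_train")) {
    target <- pattern_summary(target, isi_binwidth = config$isi_binwidth,
                              discard_ms = config$discard_ms)
  }
  runs <- lapply(seq_len(n_runs), function(i) {
    ga_run(target, mode = mode, config = config,
           seed = (seed + (i - 1) * 7919) %% 2147483647,
           base_params = base_params)
  })
  sc <- vapply(runs, function(r) r$score, numeric(1))
  best_idx <- order(sc)[seq_len(n_best)]
  pm <- vapply(runs[best_idx], function(r) r$params,
               numeric(length(runs[[1]]$params)))
  if (is.null(dim(pm))) pm <- matrix(pm, nrow = 1,
                                     dimnames = list(names(runs[[1]]$params)))
  list(params = apply(pm, 1, median), spread = apply(pm, 1, stats::sd),
       runs = runs, best_idx = best_idx)
}

#' Compare post-spike potential combinations for a target
#'
#' Fits the target with an HAP only, HAP + AHP, and HAP + DAP, and reports
#' the scores, component distances and winning mode. A target whose IoD
#' increases with binwidth needs a DAP; one whose IoD decreases needs an
#' AHP.
#'
#' @inheritParams consensus_fit
#' @param n_runs,n_best Consensus protocol per mode (1/1 runs a single GA
#'   per mode).
#' @return List with `best_mode`, `scores` (named vector) and `fits` (one
#'   consensus result per mode).
#' @export
mode_comparison <- function(target, config = ga_config(), n_runs = 1,
                            n_best = 1, seed = 1,
                            base_params = neuron_params()) {
  modes <- c("HAP", "HAP+AHP", "HAP+DAP")
  fits <- lapply(modes, function(m) {
    consensus_fit(target, mode = m, config = config, n_runs = n_runs,
                  n_best = n_best, seed = seed, base_params = base_params)
  })
  names(fits) <- modes
  scores <- vapply(fits, function(f) min(vapply(f$runs, `[[`, numeric(1),
                                                "score")), numeric(1))
  list(best_mode = names(which.min(scores)), scores = scores, fits = fits)
}
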