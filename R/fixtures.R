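#' Generate synthetic spike trains with known statistical structure
#'
#' Ground-truth generators for validating the analysis functions: trains
#' whose ISI distribution, IoD and spectral content are known analytically.
#'
#' Kinds:
#' * `"poisson"` - homogeneous Poisson at `rate_hz` (IoD 1 at every
#'   binwidth, exponential ISIs).
#' * `"regular"` - perfectly periodic (IoD near 0, single-ISI histogram).
#' * `"gamma"` - renewal process with gamma ISIs of the given `shape` and
#'   mean `1000 / rate_hz` ms (shape > 1 more regular than Poisson).
#' * `"burst"` - alternating silent / Poisson-active epochs
#'   (`epoch_s` each); clustered spiking, IoD > 1 growing with binwidth.
#' * `"sinusoid"` - inhomogeneous Poisson with rate
#'   `rate_hz * (1 + depth * sin(2 pi f_hz t))`, generated by thinning
#'   (exact for bounded rate functions); dominant population frequency
#'   `f_hz`.
#'
#' @param kind One of `"poisson"`, `"regular"`, `"gamma"`, `"burst"`,
#'   `"sinusoid"`.
#' @param rate_hz Base firing rate (Hz).
#' @param duration_s Train length (s).
#' @param seed Integer seed (deterministic output per seed).
#' @param shape Gamma shape (kind `"gamma"`).
#' @param epoch_s Epoch length (kind `"burst"`).
#' @param depth,f_hz Modulation depth in `[0, 1]` and frequency (kind
#'   `"sinusoid"`).
#' @return A [spike_train()] over `[0, duration_s * 1000]` ms.
#' @examples
#' st <- synthetic_train("poisson", rate_hz = 5, duration_s = 100, seed = 1)
#' iod(st, 1)
#' @export
synthetic_train <- function(kind = c("poisson", "regular", "gamma", "burst",
                                     "sinusoid"),
                            rate_hz, duration_s, seed = 1, shape = 4,
                            epoch_s = 5, depth = 0.8, f_hz = 3) {
  kind <- match.arg(kind)
  if (rate_hz < 0 || duration_s <= 0) stop("invalid rate or duration")
  dur_ms <- duration_s * 1000
  times <- local_seed(seed, switch(kind,
    poisson = {
      n_exp <- rate_hz * duration_s
      t <- cumsum(rexp(ceiling(n_exp + 6 * sqrt(n_exp + 10)) + 10,
                       rate_hz / 1000))
      while (length(t) && t[length(t)] < dur_ms) {
        t <- c(t, t[length(t)] + cumsum(rexp(100, rate_hz / 1000)))
      }
      t[t <= dur_ms]
    },
    regular = {
      if (rate_hz == 0) numeric(0) else seq(1000 / rate_hz, dur_ms,
                                            by = 1000 / rate_hz)
    },
    gamma = {
      mean_isi <- 1000 / rate_hz
      n_exp <- rate_hz * duration_s
      t <- cumsum(rgamma(ceiling(n_exp + 6 * sqrt(n_exp + 10)) + 10,
                         shape = shape, rate = shape / mean_isi))
      while (length(t) && t[length(t)] < dur_ms) {
        t <- c(t, t[length(t)] +
                 cumsum(rgamma(100, shape = shape, rate = shape / mean_isi)))
      }
      t[t <= dur_ms]
    },
    burst = {
      # active epochs are the odd-numbered ones
      t <- numeric(0)
      start <- epoch_s * 1000
      while (start < dur_ms) {
        seg <- start + cumsum(rexp(ceiling(rate_hz * epoch_s * 2) + 20,
                                   rate_hz / 1000))
        t <- c(t, seg[seg <= min(start + epoch_s * 1000, dur_ms)])
        start <- start + 2 * epoch_s * 1000
      }
      t
    },
    sinusoid = {
      if (depth < 0 || depth > 1) stop("depth must be in [0, 1]")
      rmax <- rate_hz * (1 + depth)
      cand <- cumsum(rexp(ceiling(rmax * duration_s +
                                    6 * sqrt(rmax * duration_s + 10)) + 10,
                          rmax / 1000))
      while (length(cand) && cand[length(cand)] < dur_ms) {
        cand <- c(cand, cand[length(cand)] + cumsum(rexp(100, rmax / 1000)))
      }
      cand <- cand[cand <= dur_ms]
      keep <- runif(length(cand)) <
        (rate_hz * (1 + depth * sin(2 * pi * f_hz * cand / 1000))) / rmax
      cand[keep]
    }))
  spike_train(unique(times), duration = dur_ms)
}
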