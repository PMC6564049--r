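# Naive, loop-based reference implementations of the spike statistics,
# kept deliberately independent of the package's vectorised versions.

oracle_isi_counts <- function(times, binwidth) {
  isi <- numeric(0)
  for (j in seq_len(length(times) - 1)) isi <- c(isi, times[j + 1] - times[j])
  nb <- max(floor(isi / binwidth)) + 1
  counts <- integer(nb)
  for (x in isi) {
    b <- floor(x / binwidth) + 1
    counts[b] <- counts[b] + 1
  }
  counts
}

oracle_hazard <- function(times, binwidth) {
  isi <- diff(times)
  nb <- max(floor(isi / binwidth)) + 1
  h <- numeric(nb)
  for (b in seq_len(nb)) {
    left <- (b - 1) * binwidth
    denom <- sum(isi >= left)
    num <- sum(isi >= left & isi < left + binwidth)
    h[b] <- if (denom > 0) num / denom else NA_real_
  }
  h
}

oracle_iod <- function(times, t0, duration, binwidth_ms) {
  nb <- floor((duration - t0) / binwidth_ms)
  counts <- integer(nb)
  for (b in seq_len(nb)) {
    lo <- t0 + (b - 1) * binwidth_ms
    hi <- t0 + b * binwidth_ms
    counts[b] <- sum(times > lo & times <= hi)
  }
  var(counts) / mean(counts)
}

oracle_psp_convolution <- function(times, duration_ms, amplitude, half_life) {
  # brute-force kernel sum: a * 2^(-t/lambda) evaluated at 1-ms bin ends
  n <- floor(duration_ms)
  out <- numeric(n)
  for (k in seq_len(n)) {
    tk <- k
    past <- times[times <= tk]
    # spikes land in bins; a spike in bin j contributes from bin j onwards
    bins <- ceiling(past)
    bins[bins == 0] <- 1
    out[k] <- sum(amplitude * 2^(-(tk - bins) / half_life))
  }
  out
}

oracle_xcorr <- function(a, b, lag, bw) {
  breaks <- seq(-lag, lag, by = bw)
  counts <- numeric(length(breaks) - 1)
  for (ta in a) for (tb in b) {
    d <- tb - ta
    if (d >= -lag && d <= lag) {
      k <- min(length(counts), max(1, findInterval(d, breaks,
                                                   rightmost.closed = TRUE)))
      counts[k] <- counts[k] + 1
    }
  }
  counts
}

# Small deterministic fixture used across oracle tests
fixture_100_spikes <- function(seed = 5) {
  synthetic_train("poisson", rate_hz = 2, duration_s = 52, seed = seed)
}
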