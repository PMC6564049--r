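#' Interspike-interval histogram
#'
#' ISIs are binned by `floor(isi / binwidth)`; bin `b` covers
#' `[(b-1) * binwidth, b * binwidth)` ms. With `normalise = TRUE` the counts
#' are scaled to total 10000, which makes trains with different spike counts
#' comparable (the convention used by the fit score).
#'
#' @param train A [spike_train()] with at least 2 spikes.
#' @param binwidth Bin width in ms (5 for fitting, 10 for display).
#' @param normalise Scale counts to total 10000.
#' @return An `isi_histogram`: list with `binwidth`, `counts` (raw),
#'   `norm_counts` (present when normalised), `mids` (bin centres, ms) and
#'   `n_intervals`.
#' @export
isi_histogram <- function(train, binwidth = 5, normalise = FALSE) {
  stopifnot(inherits(train, "spike_train"))
  if (length(train$times) < 2) {
    stop("need at least 2 spikes to form intervals (silent cell)")
  }
  isi <- diff(train$times)
  bin <- floor(isi / binwidth) + 1L
  counts <- tabulate(bin, nbins = max(bin))
  out <- list(binwidth = binwidth, counts = counts,
              mids = (seq_along(counts) - 0.5) * binwidth,
              n_intervals = length(isi))
  if (normalise) out$norm_counts <- counts / sum(counts) * 10000
  structure(out, class = "isi_histogram")
}

#' Hazard function from an ISI histogram
#'
#' Converts the absolute interval probabilities into conditional ones:
#' `hazard[b] = count[b] / (number of intervals of length >= left edge of
#' b)`, i.e. the probability of firing in bin `b` given survival to its left
#' edge. Bins whose denominator is zero are `NA`.
#'
#' @param hist An [isi_histogram()] (raw counts are used).
#' @return A `hazard_function`: list with `binwidth`, `hazard` (values in
#'   `[0, 1]`), `survivors` (denominators) and `mids`.
#' @export
hazard_fn <- function(hist) {
  stopifnot(inherits(hist, "isi_histogram"))
  surv <- hist$n_intervals - c(0, cumsum(hist$counts))[seq_along(hist$counts)]
  h <- ifelse(surv > 0, hist$counts / surv, NA_real_)
  structure(list(binwidth = hist$binwidth, hazard = h, survivors = surv,
                 mids = hist$mids),
            class = "hazard_function")
}

#' Index of dispersion of firing rate
#'
#' Variance over mean of spike counts in successive bins that tile the
#' recording window from its start (`t0`); a trailing partial bin is
#' discarded. Poisson spiking gives 1 at every binwidth, regular spiking
#' below 1, and clustered spiking above 1 with strong binwidth dependence.
#'
#' @param train A [spike_train()].
#' @param binwidth_s Bin width in seconds.
#' @return IoD value (`NA` when fewer than 2 bins fit or the train is
#'   empty).
#' @export
iod <- function(train, binwidth_s) {
  stopifnot(inherits(train, "spike_train"))
  bw <- binwidth_s * 1000
  nb <- floor((train$duration - train$t0) / bw)
  if (nb < 2 || length(train$times) == 0) return(NA_real_)
  edges <- train$t0 + bw * (0:nb)
  keep <- train$times > edges[1] & train$times <= edges[nb + 1]
  counts <- tabulate(findInterval(train$times[keep], edges,
                                  left.open = TRUE, rightmost.closed = TRUE),
                     nbins = nb)
  m <- mean(counts)
  if (m == 0) return(NA_real_)
  var(counts) / m
}

#' IoD across the standard range of binwidths
#'
#' @param train A [spike_train()].
#' @param binwidths_s Binwidths in seconds (default 0.5, 1, 2, 4, 6, 8, 10).
#' @return Named numeric vector of IoD values.
#' @export
iod_range <- function(train, binwidths_s = c(0.5, 1, 2, 4, 6, 8, 10)) {
  vapply(binwidths_s, function(b) iod(train, b), numeric(1)) |>
    stats::setNames(paste0(binwidths_s, "s"))
}

#' Summed population spike counts
#'
#' @param trains List of [spike_train()] sharing a recording window.
#' @param binwidth_ms Bin width (ms), default 1.
#' @return Numeric vector of summed counts per bin over `[t0, duration]`.
#' @export
population_rate <- function(trains, binwidth_ms = 1) {
  stopifnot(length(trains) > 0)
  t0 <- trains[[1]]$t0
  dur <- trains[[1]]$duration
  nb <- floor((dur - t0) / binwidth_ms)
  edges <- t0 + binwidth_ms * (0:nb)
  out <- numeric(nb)
  for (tr in trains) {
    stopifnot(inherits(tr, "spike_train"))
    tt <- tr$times[tr$times > edges[1] & tr$times <= edges[nb + 1]]
    if (length(tt)) {
      out <- out + tabulate(findInterval(tt, edges, left.open = TRUE,
                                         rightmost.closed = TRUE), nbins = nb)
    }
  }
  out
}

#' Simulated postsynaptic signal of a population
#'
#' Models the input potential a downstream neuron would receive if every
#' spike in the population generated an EPSP of fixed amplitude decaying
#' exponentially with the given half-life: an exponential-kernel filtering
#' of the 1-ms binned summed spike counts (a smoothed version of the
#' population activity).
#'
#' @param trains List of [spike_train()].
#' @param amplitude EPSP amplitude (mV), default 3.
#' @param half_life PSP half-life (ms), default 7.5.
#' @param binwidth_ms Sampling step (ms), default 1.
#' @return Numeric vector, one value per bin (mV).
#' @export
postsynaptic_signal <- function(trains, amplitude = 3, half_life = 7.5,
                                binwidth_ms = 1) {
  counts <- population_rate(trains, binwidth_ms)
  decay <- 2^(-binwidth_ms / half_life)
  as.numeric(stats::filter(amplitude * counts, decay, method = "recursive"))
}

#' Spike-triggered average of a recorded trace
#'
#' Mean of trace segments aligned on spike times; used e.g. to reveal the
#' subthreshold rhythm driving an oscillatory neuron. Spikes whose window
#' would extend beyond the trace are dropped (and counted).
#'
#' @param trace Numeric vector sampled every `dt_ms` from time 0.
#' @param train A [spike_train()] on the same clock.
#' @param window_ms Half-width of the window (ms).
#' @param dt_ms Sampling step of `trace` (ms).
#' @return List with `lag_ms`, `mean` (the average waveform), `n_used` and
#'   `n_dropped`.
#' @export
spike_triggered_average <- function(trace, train, window_ms, dt_ms = 1) {
  stopifnot(inherits(train, "spike_train"))
  w <- as.integer(round(window_ms / dt_ms))
  idx <- as.integer(round(train$times / dt_ms))
  ok <- idx - w >= 1 & idx + w <= length(trace)
  used <- idx[ok]
  if (length(used) == 0) stop("no spikes with a complete window")
  acc <- numeric(2 * w + 1)
  for (i in used) acc <- acc + trace[(i - w):(i + w)]
  list(lag_ms = seq(-w, w) * dt_ms, mean = acc / length(used),
       n_used = length(used), n_dropped = sum(!ok))
}

#' Cross-correlogram of two spike trains
#'
#' Histogram of time differences `t_B - t_A` over all spike pairs within
#' the lag window.
#'
#' @param train_a,train_b [spike_train()] objects with overlapping windows.
#' @param lag_ms Maximum absolute lag (ms).
#' @param binwidth_ms Bin width (ms).
#' @return List with `lag` (bin centres) and `counts`.
#' @export
crosscorrelogram <- function(train_a, train_b, lag_ms = 100, binwidth_ms = 2) {
  stopifnot(inherits(train_a, "spike_train"), inherits(train_b, "spike_train"))
  a <- train_a$times
  b <- train_b$times
  breaks <- seq(-lag_ms, lag_ms, by = binwidth_ms)
  counts <- numeric(length(breaks) - 1)
  lo <- 1L
  for (ta in a) {
    while (lo <= length(b) && b[lo] < ta - lag_ms) lo <- lo + 1L
    j <- lo
    while (j <= length(b) && b[j] <= ta + lag_ms) {
      d <- b[j] - ta
      k <- min(length(counts), max(1L, findInterval(d, breaks,
                                                    rightmost.closed = TRUE)))
      counts[k] <- counts[k] + 1
      j <- j + 1L
    }
  }
  list(lag = breaks[-length(breaks)] + binwidth_ms / 2, counts = counts)
}

#' Dominant oscillation frequency of a population rate series
#'
#' Averaged periodogram (Welch, 50-s segments with half overlap, mean
#' removed per segment) of the binned population counts; returns the
#' frequency of the maximum spectral power within 0.5-20 Hz. The peak is
#' flagged non-significant when it is below 4 times the median spectral
#' power in the search band (flat spectrum).
#'
#' @param counts Numeric vector of binned spike counts.
#' @param dt_ms Bin width of `counts` (ms), default 1.
#' @param fmin,fmax Search band (Hz).
#' @param segment_s Welch segment length (s).
#' @return List with `frequency` (Hz), `significant` (logical), `peak_power`
#'   and `median_power`.
#' @export
oscillation_frequency <- function(counts, dt_ms = 1, fmin = 0.5, fmax = 20,
                                  segment_s = 50) {
  seg <- as.integer(round(segment_s * 1000 / dt_ms))
  if (length(counts) < seg) stop("series shorter than one Welch segment")
  step <- seg %/% 2L
  starts <- seq(1L, length(counts) - seg + 1L, by = step)
  pow <- numeric(seg)
  for (s in starts) {
    x <- counts[s:(s + seg - 1L)]
    x <- x - mean(x)
    pow <- pow + Mod(fft(x))^2
  }
  pow <- pow / length(starts)
  freq <- (seq_len(seg) - 1) / (seg * dt_ms / 1000)
  band <- freq >= fmin & freq <= fmax
  fb <- freq[band]
  pb <- pow[band]
  imax <- which.max(pb)
  med <- median(pb)
  list(frequency = fb[imax], significant = pb[imax] >= 4 * med,
       peak_power = pb[imax], median_power = med)
}

#' Segment a population rate series into slow and fast states
#'
#' Smooths the per-neuron population mean rate with a moving-average window
#' and thresholds it into two states; intervals shorter than the minimum
#' duration are merged into their neighbours. Used to quantify bistable
#' switching.
#'
#' @param counts Binned summed spike counts of the population.
#' @param n_neurons Population size (to express rates per neuron).
#' @param dt_ms Bin width of `counts` (ms).
#' @param threshold State boundary (spikes/s per neuron), default 3 (the
#'   geometric midpoint of the slow ~0.85 and fast ~6 spikes/s states).
#' @param min_dur_s Minimum state duration (s), default 10.
#' @param smooth_s Moving-average window (s), default 10.
#' @return Data frame with columns `state` ("slow"/"fast"), `start_s`,
#'   `end_s`, `mean_rate` (spikes/s per neuron over the interval).
#' @export
segment_bistable_states <- function(counts, n_neurons, dt_ms = 1,
                                    threshold = 3, min_dur_s = 10,
                                    smooth_s = 10) {
  rate <- counts / n_neurons / (dt_ms / 1000)
  k <- max(1L, as.integer(round(smooth_s * 1000 / dt_ms)))
  sm <- as.numeric(stats::filter(rate, rep(1 / k, k), sides = 2))
  # extend the running mean to the edges
  first <- which(!is.na(sm))[1]
  last <- max(which(!is.na(sm)))
  sm[seq_len(first - 1)] <- sm[first]
  sm[seq(last + 1, length.out = length(sm) - last)] <- sm[last]
  fast <- sm > threshold
  r <- rle(fast)
  # merge runs shorter than min_dur into the previous state
  min_len <- min_dur_s * 1000 / dt_ms
  vals <- r$values
  lens <- r$lengths
  i <- 1L
  while (i <= length(vals)) {
    if (lens[i] < min_len && length(vals) > 1) {
      if (i == 1L) {
        lens[2] <- lens[2] + lens[1]
        vals <- vals[-1]; lens <- lens[-1]
      } else {
        lens[i - 1] <- lens[i - 1] + lens[i]
        vals <- vals[-i]; lens <- lens[-i]
        # re-merge neighbours that now agree
        if (i - 1 < length(vals) && vals[i - 1] == vals[i]) {
          lens[i - 1] <- lens[i - 1] + lens[i]
          vals <- vals[-i]; lens <- lens[-i]
        }
        i <- i - 1L
      }
    } else {
      i <- i + 1L
    }
  }
  ends <- cumsum(lens)
  starts <- c(0, ends[-length(ends)])
  out <- data.frame(
    state = ifelse(vals, "fast", "slow"),
    start_s = starts * dt_ms / 1000,
    end_s = ends * dt_ms / 1000)
  out$mean_rate <- vapply(seq_len(nrow(out)), function(i) {
    mean(rate[(starts[i] + 1):ends[i]])
  }, numeric(1))
  out
}

#' Locate modal peaks of an ISI histogram
#'
#' Lightly smooths the histogram (moving average) and reports local maxima
#' above a prominence threshold, enforcing a minimum separation (the
#' highest peak in a conflict wins). Used to read off the burst and rhythm
#' modes of network-patterned neurons.
#'
#' @param hist An [isi_histogram()].
#' @param min_ms Ignore peaks below this interval (ms), default 0.
#' @param smooth_bins Moving-average width in bins (odd), default 5.
#' @param min_frac Minimum peak height as a fraction of the tallest
#'   considered bin, default 0.15.
#' @param min_sep_ms Minimum separation between reported peaks (ms).
#' @return Numeric vector of mode locations (bin centres, ms).
#' @export
isi_modes <- function(hist, min_ms = 0, smooth_bins = 5, min_frac = 0.15,
                      min_sep_ms = 150) {
  stopifnot(inherits(hist, "isi_histogram"))
  x <- as.numeric(stats::filter(hist$counts, rep(1 / smooth_bins, smooth_bins),
                                sides = 2))
  x[is.na(x)] <- 0
  cand <- which(x > c(-Inf, head(x, -1)) & x >= c(tail(x, -1), -Inf))
  cand <- cand[hist$mids[cand] >= min_ms]
  if (length(cand) == 0) return(numeric(0))
  cand <- cand[x[cand] >= min_frac * max(x[hist$mids >= min_ms])]
  # enforce separation, keeping taller peaks first
  cand <- cand[order(-x[cand])]
  kept <- integer(0)
  for (b in cand) {
    if (all(abs(hist$mids[b] - hist$mids[kept]) >= min_sep_ms)) {
      kept <- c(kept, b)
    }
  }
  sort(hist$mids[kept])
}

#' Full spike-pattern summary of a train
#'
#' The triple used both for phenotyping and fit scoring: 5-ms ISI histogram
#' (normalised to 10000), hazard function, and IoD range, plus the mean
#' rate. An initial transient is discarded by default before computing the
#' statistics.
#'
#' @param train A [spike_train()].
#' @param isi_binwidth ISI bin width (ms), default 5.
#' @param discard_ms Initial transient to discard (ms), default 5000.
#' @return A `pattern_summary`: list with `isi` ([isi_histogram()],
#'   normalised), `hazard` ([hazard_fn()]), `iod` (named vector), `rate`
#'   (spikes/s) and `n_spikes`.
#' @export
pattern_summary <- function(train, isi_binwidth = 5, discard_ms = 5000) {
  stopifnot(inherits(train, "spike_train"))
  if (discard_ms > 0 && train$duration - train$t0 > 2 * discard_ms) {
    train <- window_train(train, train$t0 + discard_ms)
  }
  hist <- isi_histogram(train, binwidth = isi_binwidth, normalise = TRUE)
  structure(list(isi = hist, hazard = hazard_fn(hist),
                 iod = iod_range(train), rate = mean_rate(train),
                 n_spikes = length(train$times)),
            class = "pattern_summary")
}
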