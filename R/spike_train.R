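#' Spike train container
#'
#' A spike train is the universal currency between the simulator, the
#' analysis functions and the fitter: an ordered vector of event times in
#' milliseconds together with the recording window.
#'
#' @param times Numeric vector of spike times (ms), strictly increasing.
#' @param duration End of the recording window (ms). Defaults to the last
#'   spike time.
#' @param t0 Start of the recording window (ms), default 0. Statistics that
#'   tile the record into bins (e.g. [iod()]) tile from `t0`, so shifting a
#'   train and its window together leaves them unchanged.
#' @return An object of class `spike_train` with fields `times`, `t0` and
#'   `duration`.
#' @examples
#' st <- spike_train(c(10, 30, 120), duration = 1000)
#' mean_rate(st)
#' @export
spike_train <- function(times, duration = NULL, t0 = 0) {
  times <- as.numeric(times)
  if (anyNA(times)) stop("spike times contain NA")
  if (is.unsorted(times, strictly = TRUE)) {
    stop("spike times must be strictly increasing")
  }
  if (is.null(duration)) duration <- if (length(times)) times[length(times)] else t0
  duration <- as.numeric(duration)
  if (length(times) && (times[1] < t0 || times[length(times)] > duration)) {
    stop("spike times must lie within [t0, duration]")
  }
  structure(list(times = times, t0 = t0, duration = duration),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.1f s (%.3f spikes/s)\n",
              length(x$times), (x$duration - x$t0) / 1000, mean_rate(x)))
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$times)

#' Mean firing rate of a spike train
#'
#' @param train A [spike_train()].
#' @return Mean rate in spikes/s over the recording window.
#' @export
mean_rate <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  dur_s <- (train$duration - train$t0) / 1000
  if (dur_s <= 0) return(NA_real_)
  length(train$times) / dur_s
}

#' Restrict a spike train to a time window
#'
#' Keeps spikes with `from < t <= to` and re-references the recording window
#' to `[from, to]`. Used to discard initial transients before computing
#' statistics.
#'
#' @param train A [spike_train()].
#' @param from,to Window bounds (ms); `to` defaults to the train's duration.
#' @export
window_train <- function(train, from, to = train$duration) {
  stopifnot(inherits(train, "spike_train"))
  keep <- train$times > from & train$times <= to
  spike_train(train$times[keep], duration = to, t0 = from)
}

#' Shift a spike train (and its recording window) in time
#'
#' @param train A [spike_train()].
#' @param by Offset in ms.
#' @export
shift_train <- function(train, by) {
  stopifnot(inherits(train, "spike_train"))
  spike_train(train$times + by, duration = train$duration + by,
              t0 = train$t0 + by)
}

#' Interspike intervals of a train
#'
#' @param train A [spike_train()].
#' @return Numeric vector of ISIs (ms); length `n_spikes - 1`.
#' @export
isis <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  diff(train$times)
}
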