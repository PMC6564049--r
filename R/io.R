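#' Read a spike-time text file
#'
#' One event time per line, no header, strictly increasing. Matches the
#' dialect of deposited in-vivo spike-time datasets. Times in seconds are
#' converted to ms; with `unit = "auto"` the unit is guessed from the
#' median ISI (recorded trains measured in seconds have median intervals
#' well below 100 in file units).
#'
#' @param path File path.
#' @param unit `"ms"`, `"s"`, or `"auto"`.
#' @param duration Recording length (ms); defaults to the last spike time.
#' @return A [spike_train()] in ms.
#' @export
read_spike_times <- function(path, unit = c("ms", "s", "auto"),
                             duration = NULL) {
  unit <- match.arg(unit)
  x <- scan(path, what = numeric(), quiet = TRUE)
  if (anyNA(x)) stop("non-numeric spike times in ", path)
  bad <- which(diff(x) <= 0)
  if (length(bad)) {
    stop("spike times not strictly increasing at line(s) ",
         paste(bad + 1, collapse = ", "), " of ", path)
  }
  if (length(x) && x[1] < 0) stop("negative spike time at line 1 of ", path)
  if (unit == "auto") {
    unit <- if (length(x) > 1 && median(diff(x)) < 50) "s" else "ms"
  }
  if (unit == "s") x <- x * 1000
  spike_train(x, duration = duration)
}

#' Write a spike train as a spike-time text file
#'
#' @param train A [spike_train()].
#' @param path Output path.
#' @param unit `"ms"` or `"s"`.
#' @param digits Decimal places (default 1, i.e. 0.1-ms resolution in ms).
#' @export
write_spike_times <- function(train, path, unit = c("ms", "s"), digits = 1) {
  stopifnot(inherits(train, "spike_train"))
  unit <- match.arg(unit)
  x <- if (unit == "s") train$times / 1000 else train$times
  writeLines(formatC(x, format = "f", digits = digits), path)
  invisible(path)
}

#' Read a model/experiment configuration file
#'
#' YAML files whose keys use the model's parameter names (`I_re`, `k_HAP`,
#' `lambda_HAP`, `vmn1`, `esyn_1`, `syntrans`, `delta_min`, ...). A
#' `type1:` / `type2:` block holds neuron parameters; top-level keys hold
#' network and experiment settings.
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Build network parameters from a configuration list
#'
#' @param cfg A list as returned by [read_config()].
#' @return A [network_params()] object.
#' @export
config_to_network <- function(cfg) {
  np_args <- function(block) {
    if (is.null(block)) return(NULL)
    do.call(neuron_params, block)
  }
  keys <- c("vmn1", "vmn2", "esyn_1", "esyn_12", "synweight_1", "syntrans",
            "delta_min", "delta_range", "n_h")
  args <- cfg[intersect(names(cfg), keys)]
  if (!is.null(cfg$type1)) args$type1 <- np_args(cfg$type1)
  if (!is.null(cfg$type2)) args$type2 <- np_args(cfg$type2)
  do.call(network_params, args)
}

#' Export a pattern summary as delimited text tables
#'
#' Writes `isi.tsv` (bin centre, raw count, normalised count), `hazard.tsv`
#' (bin centre, hazard, survivors) and `iod.tsv` (binwidth s, IoD) into a
#' directory, mirroring the standard analysis panels.
#'
#' @param summary A [pattern_summary()].
#' @param dir Output directory (created if needed).
#' @export
write_summary_tables <- function(summary, dir) {
  stopifnot(inherits(summary, "pattern_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(data.frame(isi_ms = summary$isi$mids,
                         count = summary$isi$counts,
                         norm = summary$isi$norm_counts),
              file.path(dir, "isi.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(data.frame(isi_ms = summary$hazard$mids,
                         hazard = summary$hazard$hazard,
                         survivors = summary$hazard$survivors),
              file.path(dir, "hazard.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(data.frame(binwidth_s = sub("s$", "", names(summary$iod)),
                         iod = as.numeric(summary$iod)),
              file.path(dir, "iod.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(dir)
}
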