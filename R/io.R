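#' Read and write spike tables
#'
#' Spike data are exchanged as CSV tables with columns `neuron_id` and
#' `time_s`, plus a JSON metadata sidecar written by
#' [write_sim_metadata()].
#'
#' @param x an `aqif_sim` or a data frame with `neuron`/`time_ms` columns.
#' @param path CSV file path.
#' @return `write_spike_csv` returns `path` invisibly.
#' @export
write_spike_csv <- function(x, path) {
  spikes <- if (inherits(x, "aqif_sim")) x$spikes else x
  utils::write.csv(data.frame(neuron_id = spikes$neuron,
                              time_s = spikes$time_ms / 1000),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @param n_neurons,duration_s raster geometry (taken from the data range
#'   when `NULL`).
#' @return `read_spike_csv` returns a data frame (`neuron`, `time_ms`)
#'   with attributes `n_neurons` and `duration_s`, ready for
#'   [bin_raster()].
#' @export
read_spike_csv <- function(path, n_neurons = NULL, duration_s = NULL) {
  d <- utils::read.csv(path)
  stopifnot(all(c("neuron_id", "time_s") %in% names(d)))
  if (nrow(d) == 0 && (is.null(n_neurons) || is.null(duration_s)))
    stop("empty spike table: n_neurons and duration_s must be given")
  out <- data.frame(neuron = as.integer(d$neuron_id),
                    time_ms = d$time_s * 1000)
  attr(out, "n_neurons") <- if (is.null(n_neurons)) max(out$neuron)
    else as.integer(n_neurons)
  attr(out, "duration_s") <- if (is.null(duration_s)) max(d$time_s)
    else duration_s
  out
}

#' @rdname write_spike_csv
#' @param sim an `aqif_sim`.
#' @param seed the seed the simulation was run with.
#' @export
write_sim_metadata <- function(sim, path, seed = NA) {
  meta <- list(params = unclass(sim$params), n_neurons = sim$n_neurons,
               duration_s = sim$duration_s, dt_ms = sim$dt_ms, seed = seed)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write summary statistics to JSON
#'
#' @param stats an `aqif_stats` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(stats, path) {
  out <- list(mean_rate = stats$mean_rate,
              mean_pairwise_corr = stats$mean_pairwise_corr,
              pct_silence = stats$pct_silence,
              sorted_mua = stats$sorted_mua,
              acf = list(lags_ms = stats$acf$lags_ms, acf = stats$acf$acf,
                         fit = as.list(stats$acf$fit)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
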