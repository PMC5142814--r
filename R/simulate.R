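#' Simulate the adaptive spiking network
#'
#' Integrates the conductance-based quadratic integrate-and-fire network
#' with Euler's method at the fixed step `params$dt` (0.75 ms). The
#' subthreshold voltage of neuron i obeys
#' `tau_m dV/dt = -(V - E_L)(V - V_th) - gE (V - E_E) - gI (V - E_I) - gA (V - E_A)`,
#' with a spike recorded and `V` reset to `V_reset` whenever the
#' post-update voltage exceeds `V_th`, and `V` clamped at `E_I` after every
#' update. The excitatory conductance is driven by recurrent spikes through
#' `J`, the tonic input `b` and any external drive; the global inhibitory
#' conductance by `wI (exp(c * n_spikes) - 1)` where `n_spikes` is the
#' previous step's population spike count; the adaptation conductance by
#' each neuron's own spikes. Spike impulses enter the conductances of the
#' following step (synchronous update); every conductance integrates
#' `tau dg/dt = -g + drive` by forward Euler, so spike terms carry the same
#' `dt / tau` factor as the decay and the continuous drives.
#'
#' The integration is fully deterministic given the connectivity, tonic
#' input, initial state, inserted spikes and external input; randomness
#' enters only through the seeded construction of those inputs.
#'
#' @param params an [model_params()] object.
#' @param J connectivity: an [build_connectivity()] result or a sparse
#'   matrix; built from `seed` if `NULL`.
#' @param b tonic input: a [draw_tonic_input()] result or numeric vector;
#'   drawn from `seed + 1` if `NULL`.
#' @param duration_s simulated time returned, in seconds (after burn-in).
#' @param external_input `NULL`, a neuron x time matrix of non-negative
#'   drive sampled at `dt` resolution (recycled cyclically if shorter than
#'   the run), or an `aqif_external_input` object.
#' @param init initial state: `NULL` (voltages uniform on
#'   `[E_L, V_reset]` from `seed + 2`, conductances zero) or a list with
#'   elements `V`, `gE`, `gI`, `gA`, `gI_glob` as returned in `$final`.
#' @param inserted_spikes `NULL` or a data frame / 2-column matrix of
#'   `(neuron, time_ms)` spikes to force (the neuron's voltage is pushed
#'   above threshold at that step, so reset and all couplings follow).
#'   Times are relative to the start of integration (burn-in included).
#' @param burn_in_s initial transient discarded from the returned spikes;
#'   times are shifted so 0 marks the end of burn-in.
#' @param seed integer seed used for any defaulted random ingredient.
#' @param record_neuron 1-based index of a neuron whose voltage and
#'   conductance traces are recorded each step (0 = none).
#' @param nmda_frac,gabab_frac,tau_slow optional slow conductance channels:
#'   every recurrent excitatory impulse is echoed into an NMDA-like channel
#'   scaled by `nmda_frac`, and every global inhibitory impulse into a
#'   GABA_B-like channel scaled by `gabab_frac`, both decaying with
#'   `tau_slow` (ms). Both fractions 0 (the default) reproduces the base
#'   model exactly; see [simulate_slow_conductances()].
#'
#' @return An object of class `aqif_sim`: a list with `spikes` (data frame
#'   `neuron`, `time_ms`), `n_neurons`, `duration_s`, `dt_ms`, `params`,
#'   `final` (state at the last step) and, if requested, `trace`.
#' @examples
#' p <- model_params()
#' sim <- simulate_network(p, duration_s = 10, burn_in_s = 2, seed = 1)
#' nrow(sim$spikes)
#' @export
simulate_network <- function(params, J = NULL, b = NULL, duration_s,
                             external_input = NULL, init = NULL,
                             inserted_spikes = NULL, burn_in_s = 5,
                             seed = 1L, record_neuron = 0L,
                             nmda_frac = 0, gabab_frac = 0, tau_slow = 100) {
  stopifnot(inherits(params, "aqif_params"), duration_s > 0, burn_in_s >= 0)
  n <- params$N
  if (is.null(J)) J <- build_connectivity(n, params$p_conn, params$wE, seed)
  if (inherits(J, "aqif_connectivity")) J <- J$J
  J <- methods::as(methods::as(J, "CsparseMatrix"), "generalMatrix")
  if (is.null(b)) b <- draw_tonic_input(n, params$b0, params$b1, seed + 1L)
  if (inherits(b, "aqif_tonic")) b <- b$b
  stopifnot(nrow(J) == n, ncol(J) == n, length(b) == n)

  if (is.null(init)) {
    set.seed(seed + 2L)
    init <- list(V = stats::runif(n, params$E_L, params$V_reset),
                 gE = numeric(n), gI = numeric(n), gA = numeric(n),
                 gI_glob = 0)
  }
  ext <- resolve_external_input(external_input, n)

  n_steps <- as.integer(round((duration_s + burn_in_s) * 1000 / params$dt))
  ins <- resolve_inserted(inserted_spikes, n, params$dt, n_steps)

  empty_p <- integer(n + 1)
  res <- simulate_core_cpp(
    n_steps, params$dt,
    rep(params$tau_m, n), params$tau_E, params$tau_I, params$tau_A,
    params$E_L, params$V_th, params$V_reset,
    params$E_E, params$E_I, params$E_A,
    J@p, J@i, J@x, empty_p, integer(0), numeric(0),
    params$wI, params$c, rep(params$wA, n), b,
    ext, nmda_frac, gabab_frac, tau_slow,
    init$V, init$gE, init$gI, init$gA, init$gI_glob,
    ins$neuron, ins$step, as.integer(record_neuron))

  finish_sim(res, params$dt, n, duration_s, burn_in_s, params)
}

# shared post-processing: drop burn-in, build the aqif_sim object
finish_sim <- function(res, dt, n, duration_s, burn_in_s, params) {
  time_ms <- res$step * dt - burn_in_s * 1000
  keep <- time_ms >= 0
  out <- list(spikes = data.frame(neuron = res$neuron[keep],
                                  time_ms = time_ms[keep]),
              n_neurons = n, duration_s = duration_s, dt_ms = dt,
              params = params, final = res$final)
  if (!is.null(res$trace)) out$trace <- res$trace
  structure(out, class = "aqif_sim")
}

resolve_external_input <- function(external_input, n) {
  if (is.null(external_input)) return(matrix(numeric(0), nrow = n, ncol = 0))
  if (inherits(external_input, "aqif_external_input"))
    external_input <- external_input$drive
  stopifnot(is.matrix(external_input), nrow(external_input) == n)
  external_input
}

resolve_inserted <- function(inserted_spikes, n, dt, n_steps) {
  if (is.null(inserted_spikes) || NROW(inserted_spikes) == 0)
    return(list(neuron = integer(0), step = integer(0)))
  m <- as.matrix(as.data.frame(inserted_spikes))
  neuron <- as.integer(m[, 1])
  step <- as.integer(round(m[, 2] / dt))
  stopifnot(all(neuron >= 1), all(neuron <= n),
            all(step >= 0), all(step < n_steps))
  o <- order(step)
  list(neuron = neuron[o], step = step[o])
}

#' @export
print.aqif_sim <- function(x, ...) {
  cat(sprintf("aqif_sim: %d neurons, %.3g s, %d spikes (%.2f spikes/s/neuron)\n",
              x$n_neurons, x$duration_s, nrow(x$spikes),
              nrow(x$spikes) / x$n_neurons / x$duration_s))
  invisible(x)
}

#' Bin spikes into a count raster
#'
#' Converts simulated spikes (or a spike table) into the neuron x bin count
#' matrix that all statistics operate on.
#'
#' @param x an `aqif_sim` object or a data frame with columns `neuron` and
#'   `time_ms`.
#' @param bin_ms bin width in ms (15 ms for all fitted statistics).
#' @param neurons optional integer vector of neurons to keep (rows of the
#'   result follow this order).
#' @param n_neurons,duration_s required when `x` is a bare spike table.
#' @return A [spike_raster()] object.
#' @export
bin_raster <- function(x, bin_ms = 15, neurons = NULL,
                       n_neurons = NULL, duration_s = NULL) {
  if (inherits(x, "aqif_sim")) {
    spikes <- x$spikes; n_neurons <- x$n_neurons; duration_s <- x$duration_s
  } else {
    spikes <- x
    stopifnot(!is.null(n_neurons), !is.null(duration_s))
  }
  if (is.null(neurons)) neurons <- seq_len(n_neurons)
  n_bins <- max(1L, as.integer(floor(duration_s * 1000 / bin_ms)))
  sel <- match(spikes$neuron, neurons)
  keep <- !is.na(sel) & spikes$time_ms < n_bins * bin_ms
  bin <- pmin(n_bins - 1L, as.integer(spikes$time_ms[keep] %/% bin_ms))
  if (any(keep)) {
    counts <- as.matrix(Matrix::sparseMatrix(
      i = sel[keep], j = bin + 1L, x = 1,
      dims = c(length(neurons), n_bins)))
    storage.mode(counts) <- "integer"
  } else {
    counts <- matrix(0L, nrow = length(neurons), ncol = n_bins)
  }
  spike_raster(counts, bin_ms)
}

#' Spike raster container
#'
#' The universal exchange type between the simulator, the statistics and
#' synthetic or real recordings: a non-negative integer count matrix with a
#' stated bin width.
#'
#' @param counts neuron x bin matrix of non-negative counts.
#' @param bin_ms bin width in ms.
#' @return An object of class `spike_raster` with fields `counts`,
#'   `bin_ms`, `n_neurons`, `duration_s`.
#' @export
spike_raster <- function(counts, bin_ms) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), bin_ms > 0)
  structure(list(counts = counts, bin_ms = bin_ms,
                 n_neurons = nrow(counts),
                 duration_s = ncol(counts) * bin_ms / 1000),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike_raster: %d neurons x %d bins (%g ms), %.3g s\n",
              x$n_neurons, ncol(x$counts), x$bin_ms, x$duration_s))
  invisible(x)
}

#' Sweep one model parameter and tabulate summary statistics
#'
#' Holds all parameters fixed at `base`, changes the named parameter across
#' `values`, simulates each point with the same connectivity and tonic
#' seeds, and returns one row of descriptive statistics per value.
#'
#' @param base an [model_params()] object.
#' @param swept_name one of `"wI"`, `"wA"`, `"wE"`, `"b1"`, `"b0"`.
#' @param values numeric vector of swept values.
#' @param duration_s simulated duration per point.
#' @param seed seed shared across rows (connectivity, tonic input, initial
#'   state and the 50-neuron subsample).
#' @param subsample number of neurons statistics are computed on
#'   (`NULL` = all).
#' @param burn_in_s discarded transient per run.
#' @return A data frame with columns `value`, `mean_rate`, `pct_silence`,
#'   `mean_corr`, `acf_decay_ms`.
#' @export
parameter_sweep <- function(base, swept_name, values, duration_s = 60,
                            seed = 1L, subsample = 50L, burn_in_s = 5) {
  if (!swept_name %in% free_param_names())
    stop("invalid argument: unknown parameter ", swept_name)
  rows <- lapply(values, function(v) {
    p <- base
    p[[swept_name]] <- v
    sim <- simulate_network(p, duration_s = duration_s, seed = seed,
                            burn_in_s = burn_in_s)
    r <- bin_raster(sim, 15)
    if (!is.null(subsample) && subsample < r$n_neurons)
      r <- subsample_neurons(r, subsample, seed = seed)
    s <- summary_stats(r)
    data.frame(value = v, mean_rate = s$mean_rate,
               pct_silence = s$pct_silence, mean_corr = s$mean_pairwise_corr,
               acf_decay_ms = s$acf$fit[["T_decay"]])
  })
  do.call(rbind, rows)
}
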