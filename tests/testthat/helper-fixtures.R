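# Shared fixtures: short simulations at the up/down example point, cached
# across tests within a run.

fig2_params <- function() model_params()   # wI=0.22 wA=0.80 wE=4.50 b1=0.03 b0=0.013

local_cache <- new.env(parent = emptyenv())

cached_sim <- function(key = "fig2_20s", duration_s = 20, seed = 1L,
                       params = fig2_params()) {
  if (is.null(local_cache[[key]]))
    local_cache[[key]] <- simulate_network(params, duration_s = duration_s,
                                           burn_in_s = 5, seed = seed)
  local_cache[[key]]
}

# bind trial x neuron x bin arrays along the trial dimension
abind_trials <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(0L, c(sum(vapply(parts, function(a) dim(a)[1], integer(1))),
                     d[2], d[3]))
  at <- 0L
  for (a in parts) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

# small Poisson raster helper
poisson_raster <- function(n_neurons, rate_hz, duration_s, bin_ms = 15,
                           seed = 1L) {
  set.seed(seed)
  n_bins <- floor(duration_s * 1000 / bin_ms)
  spike_raster(matrix(rpois(n_neurons * n_bins, rate_hz * bin_ms / 1000),
                      nrow = n_neurons), bin_ms)
}
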