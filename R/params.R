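#' Model parameters for the adaptive spiking network
#'
#' Bundles the five free parameters of the network together with its fixed
#' constants. The free parameters are the excitatory weight scale `wE`
#' (upper bound of the uniform synaptic weight draw), the global inhibitory
#' feedback strength `wI`, the adaptation strength `wA`, and the tonic input
#' baseline `b0` and spread `b1` (the per-neuron tonic drive is
#' `b0 + Exp(b1)`). All other constants -- membrane and synaptic time
#' constants, reversal potentials, threshold/reset, network size,
#' connection probability and the integration step -- are fixed.
#'
#' @param wI inhibitory feedback strength; fitting range `[0.01, 0.4]`.
#' @param wA adaptation strength; fitting range `[0.4, 1.45]`.
#' @param wE excitatory weight scale; fitting range `[2.5, 5]`.
#' @param b1 tonic input spread (mean of the exponential component);
#'   fitting range `[0.005, 0.10]`.
#' @param b0 tonic input baseline; fitting range `[0.0001, 0.05]`.
#' @param tau_m,tau_E,tau_I,tau_A membrane, excitatory, inhibitory and
#'   adaptation time constants (ms).
#' @param c gain of the exponential supralinearity of the global
#'   inhibitory feedback.
#' @param V_th,E_L,E_E,E_I,E_A,V_reset threshold, leak, excitatory,
#'   inhibitory and adaptation reversal potentials, and reset voltage
#'   (dimensionless, `V_th = 1`).
#' @param dt integration time step (ms).
#' @param N number of neurons.
#' @param p_conn connection probability.
#' @param check if `TRUE`, error when a free parameter lies outside its
#'   fitting range (parameter sweeps may legitimately exceed them).
#'
#' @return An object of class `aqif_params`: a named list of all constants.
#' @examples
#' p <- model_params()           # the up/down-state example point
#' p$wI
#' @export
model_params <- function(wI = 0.22, wA = 0.80, wE = 4.50, b1 = 0.03,
                         b0 = 0.013,
                         tau_m = 20, tau_E = 5.10, tau_I = 3.75, tau_A = 375,
                         c = 0.25, V_th = 1, E_L = 0, E_E = 2 * V_th,
                         E_I = -0.5 * V_th, E_A = -0.5 * V_th,
                         V_reset = 0.9 * V_th, dt = 0.75, N = 512L,
                         p_conn = 0.05, check = FALSE) {
  p <- list(wI = wI, wA = wA, wE = wE, b1 = b1, b0 = b0,
            tau_m = tau_m, tau_E = tau_E, tau_I = tau_I, tau_A = tau_A,
            c = c, V_th = V_th, E_L = E_L, E_E = E_E, E_I = E_I, E_A = E_A,
            V_reset = V_reset, dt = dt, N = as.integer(N), p_conn = p_conn)
  stopifnot(tau_m > 0, tau_E > 0, tau_I > 0, tau_A > 0, dt > 0,
            V_reset < V_th, N >= 2, p_conn >= 0, p_conn <= 1,
            wI >= 0, wA >= 0, wE >= 0, b0 >= 0, b1 >= 0)
  if (check) {
    r <- param_ranges()
    for (nm in names(r)) {
      if (p[[nm]] < r[[nm]][1] || p[[nm]] > r[[nm]][2])
        stop(sprintf("parameter %s = %g outside fitting range [%g, %g]",
                     nm, p[[nm]], r[[nm]][1], r[[nm]][2]))
    }
  }
  structure(p, class = "aqif_params")
}

#' Fitting ranges of the five free parameters
#'
#' @return Named list of `c(lower, upper)` ranges for `wI`, `wA`, `wE`,
#'   `b1`, `b0`.
#' @export
param_ranges <- function() {
  list(wI = c(0.01, 0.4), wA = c(0.4, 1.45), wE = c(2.50, 5.00),
       b1 = c(0.005, 0.10), b0 = c(0.0001, 0.05))
}

#' Names of the five free model parameters
#' @return Character vector `c("wI","wA","wE","b1","b0")`.
#' @export
free_param_names <- function() c("wI", "wA", "wE", "b1", "b0")

#' @export
print.aqif_params <- function(x, ...) {
  cat("Adaptive QIF network parameters\n")
  cat(sprintf("  free:  wI=%.4g wA=%.4g wE=%.4g b1=%.4g b0=%.4g\n",
              x$wI, x$wA, x$wE, x$b1, x$b0))
  cat(sprintf("  fixed: N=%d p=%.3g dt=%.3g ms; tau m/E/I/A = %g/%g/%g/%g ms; c=%g\n",
              x$N, x$p_conn, x$dt, x$tau_m, x$tau_E, x$tau_I, x$tau_A, x$c))
  invisible(x)
}

#' Read or write a model configuration as JSON
#'
#' The JSON keys mirror the `aqif_params` field names exactly, so a config
#' written by one session can be fed back unchanged.
#'
#' @param params an `aqif_params` object.
#' @param path file path.
#' @return `write_params_json` returns `path` invisibly; `read_params_json`
#'   returns an `aqif_params` object.
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(model_params, x[names(x) != "check"])
}
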