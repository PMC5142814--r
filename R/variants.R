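#' Configuration of the slow-conductance (NMDA/GABA_B) variant
#'
#' Adds long-timescale excitatory and inhibitory conductances to the base
#' network: an NMDA-like channel whose per-spike increments are a fixed
#' fraction of the AMPA (fast excitatory) increments, and a GABA_B-like
#' channel incremented by the same fraction rule from the global
#' inhibitory feedback, both decaying with `tau_NMDA`. An impulse of size
#' `w` into a channel with time constant `tau` injects integrated
#' conductance `w * tau`, so the slow channel carries
#' `nmda_fraction * tau_NMDA / tau_E` times the fast channel's integral --
#' close to 1 at the defaults, i.e. roughly the same integrated current at
#' a much longer timescale.
#'
#' @param base_params an [model_params()] object; the default is the
#'   parameter point used for the multi-timescale demonstration
#'   (`wA = 0.51`, `wE = 2.6`, `b1 = 0.008`, `b0 = 0.037`), with `wI`
#'   swept over `[0.02, 0.25]`.
#' @param nmda_fraction NMDA increment as a fraction of the AMPA increment.
#' @param gabab_fraction GABA_B increment as a fraction of the global
#'   inhibitory (GABA) increment.
#' @param tau_NMDA decay time constant (ms) shared by both slow channels.
#' @return List of class `slow_conductance_config`.
#' @export
slow_conductance_config <- function(base_params = model_params(
                                      wA = 0.51, wI = 0.1, wE = 2.6,
                                      b1 = 0.008, b0 = 0.037),
                                    nmda_fraction = 0.04,
                                    gabab_fraction = 0.02,
                                    tau_NMDA = 100) {
  stopifnot(inherits(base_params, "aqif_params"),
            nmda_fraction >= 0, nmda_fraction < 1,
            gabab_fraction >= 0, gabab_fraction < 1, tau_NMDA > 0)
  structure(list(base_params = base_params, nmda_fraction = nmda_fraction,
                 gabab_fraction = gabab_fraction, tau_NMDA = tau_NMDA),
            class = "slow_conductance_config")
}

#' Simulate the slow-conductance variant
#'
#' Identical contract to [simulate_network()] with the two slow channels
#' enabled; with both fractions zero the output is bitwise identical to the
#' base model.
#'
#' @param config a [slow_conductance_config()].
#' @param duration_s simulated duration (s).
#' @param ... passed to [simulate_network()] (`J`, `b`, `external_input`,
#'   `seed`, ...).
#' @return An `aqif_sim` object.
#' @export
simulate_slow_conductances <- function(config, duration_s, ...) {
  stopifnot(inherits(config, "slow_conductance_config"))
  simulate_network(config$base_params, duration_s = duration_s,
                   nmda_frac = config$nmda_fraction,
                   gabab_frac = config$gabab_fraction,
                   tau_slow = config$tau_NMDA, ...)
}

#' Configuration of the clustered E/I network variant
#'
#' A network of 144 clusters of 32 neurons (24 excitatory, 8 inhibitory)
#' with explicit spiking inhibitory neurons instead of the global feedback
#' term. Connection probabilities differ within and between clusters
#' (inhibitory-to-inhibitory connectivity is unclustered), adaptation acts
#' on excitatory neurons only, and the two populations have different
#' membrane time constants. Naming: `p_xy` / `s_xy` is the probability /
#' strength of connections from population `x` onto population `y`.
#'
#' @param n_clusters,n_exc_per,n_inh_per cluster layout.
#' @param p_ee_in,p_ie_in,p_ei_in within-cluster connection probabilities
#'   (E to E, I to E, E to I).
#' @param p_ee_out,p_ie_out,p_ei_out out-of-cluster probabilities.
#' @param p_ii,s_ii inhibitory-to-inhibitory probability and strength
#'   (unclustered, fixed strength).
#' @param s_ee,s_ie mean synaptic strengths (E to E, I to E); realized
#'   weights are uniform on `(0, 2 * mean)`.
#' @param s_ei mean E-to-I strength; swept over `[0.025, 0.057]` to vary
#'   the strength of inhibitory recruitment.
#' @param wA,tau_A adaptation strength (excitatory neurons) and timescale.
#' @param tau_m_E,tau_m_I,tau_E,tau_I membrane and synaptic time constants.
#' @param b0,b1 tonic input baseline and spread (same construction as the
#'   base model; the clustered demonstration does not pin these, so they
#'   default to the base model's example point).
#' @param dt integration step (ms).
#' @return List of class `clustered_net_config`; `n_neurons` is the total
#'   count with excitatory neurons first within each cluster.
#' @export
clustered_net_config <- function(n_clusters = 144L, n_exc_per = 24L,
                                 n_inh_per = 8L,
                                 p_ee_in = 0.3, p_ie_in = 0.15, p_ei_in = 0.1,
                                 p_ee_out = 0.012, p_ie_out = 0.03,
                                 p_ei_out = 0.01,
                                 p_ii = 0.01, s_ii = 0.17,
                                 s_ee = 0.024, s_ie = 0.016, s_ei = 0.041,
                                 wA = 0.45, tau_A = 220,
                                 tau_m_E = 25, tau_m_I = 5,
                                 tau_E = 6, tau_I = 3,
                                 b0 = 0.013, b1 = 0.03, dt = 0.75) {
  probs <- c(p_ee_in, p_ie_in, p_ei_in, p_ee_out, p_ie_out, p_ei_out, p_ii)
  if (any(probs < 0 | probs > 1))
    stop("invalid argument: connection probabilities must lie in [0, 1]")
  stopifnot(n_clusters >= 1, n_exc_per >= 1, n_inh_per >= 1,
            tau_A > 0, tau_m_E > 0, tau_m_I > 0, tau_E > 0, tau_I > 0)
  structure(list(n_clusters = as.integer(n_clusters),
                 n_exc_per = as.integer(n_exc_per),
                 n_inh_per = as.integer(n_inh_per),
                 n_neurons = as.integer(n_clusters * (n_exc_per + n_inh_per)),
                 p_ee_in = p_ee_in, p_ie_in = p_ie_in, p_ei_in = p_ei_in,
                 p_ee_out = p_ee_out, p_ie_out = p_ie_out,
                 p_ei_out = p_ei_out, p_ii = p_ii, s_ii = s_ii,
                 s_ee = s_ee, s_ie = s_ie, s_ei = s_ei,
                 wA = wA, tau_A = tau_A, tau_m_E = tau_m_E,
                 tau_m_I = tau_m_I, tau_E = tau_E, tau_I = tau_I,
                 b0 = b0, b1 = b1, dt = dt),
            class = "clustered_net_config")
}

# sample k ordered (src, tgt) pairs at probability p from the cross of two
# index sets, returning a 2-column matrix (source, target), self-pairs kept
# for the caller to drop
sample_pairs <- function(src, tgt, p) {
  n_pairs <- as.double(length(src)) * length(tgt)
  if (n_pairs == 0 || p <= 0)
    return(matrix(integer(0), ncol = 2))
  k <- stats::rbinom(1, n_pairs, p)
  if (k == 0) return(matrix(integer(0), ncol = 2))
  id <- sample(n_pairs, k) - 1
  cbind(src[(id %/% length(tgt)) + 1], tgt[(id %% length(tgt)) + 1])
}

#' Build the clustered network connectivity
#'
#' @param config a [clustered_net_config()].
#' @param seed integer seed.
#' @return List of class `aqif_clustered_net` with sparse matrices `J_E`
#'   (columns = outgoing synapses of excitatory neurons) and `J_I`
#'   (inhibitory neurons), `labels` (`"E"`/`"I"` per neuron), `cluster`
#'   (cluster id per neuron) and `seed`.
#' @export
build_clustered_network <- function(config = clustered_net_config(),
                                    seed = 1L) {
  stopifnot(inherits(config, "clustered_net_config"))
  set.seed(seed)
  n <- config$n_neurons
  per <- config$n_exc_per + config$n_inh_per
  cluster <- rep(seq_len(config$n_clusters), each = per)
  is_exc <- rep(c(rep(TRUE, config$n_exc_per), rep(FALSE, config$n_inh_per)),
                config$n_clusters)
  exc <- which(is_exc); inh <- which(!is_exc)

  edges_in <- function(type_src, type_tgt, p) {
    out <- vector("list", config$n_clusters)
    for (cl in seq_len(config$n_clusters)) {
      s <- which(cluster == cl & (is_exc == (type_src == "E")))
      t <- which(cluster == cl & (is_exc == (type_tgt == "E")))
      out[[cl]] <- sample_pairs(s, t, p)
    }
    do.call(rbind, out)
  }
  drop_same_cluster <- function(e)
    e[cluster[e[, 1]] != cluster[e[, 2]], , drop = FALSE]

  ee <- rbind(edges_in("E", "E", config$p_ee_in),
              drop_same_cluster(sample_pairs(exc, exc, config$p_ee_out)))
  ee <- ee[ee[, 1] != ee[, 2], , drop = FALSE]
  ei <- rbind(edges_in("E", "I", config$p_ei_in),
              drop_same_cluster(sample_pairs(exc, inh, config$p_ei_out)))
  ie <- rbind(edges_in("I", "E", config$p_ie_in),
              drop_same_cluster(sample_pairs(inh, exc, config$p_ie_out)))
  ii <- sample_pairs(inh, inh, config$p_ii)
  ii <- ii[ii[, 1] != ii[, 2], , drop = FALSE]

  # weights: uniform jitter on (0, 2 * mean), I-I fixed strength
  wt <- function(e, mean_s) 2 * mean_s * stats::runif(nrow(e))
  J_E <- Matrix::sparseMatrix(
    i = c(ee[, 2], ei[, 2]), j = c(ee[, 1], ei[, 1]),
    x = c(wt(ee, config$s_ee), wt(ei, config$s_ei)), dims = c(n, n))
  J_I <- Matrix::sparseMatrix(
    i = c(ie[, 2], ii[, 2]), j = c(ie[, 1], ii[, 1]),
    x = c(wt(ie, config$s_ie), rep(config$s_ii, nrow(ii))), dims = c(n, n))
  structure(list(J_E = J_E, J_I = J_I,
                 labels = ifelse(is_exc, "E", "I"), cluster = cluster,
                 seed = seed, config = config),
            class = "aqif_clustered_net")
}

#' Simulate the clustered network
#'
#' Deterministic integration with two membrane time constants (excitatory
#' 25 ms, inhibitory 5 ms), conductance-based inhibitory synapses with
#' reversal `E_I`, adaptation on excitatory neurons only, and no global
#' feedback term. Threshold, reset and reversal constants are shared with
#' the base model.
#'
#' @param config a [clustered_net_config()].
#' @param duration_s simulated duration (s).
#' @param external_input `NULL` or neuron x time drive matrix (tiled).
#' @param net optional prebuilt [build_clustered_network()] (rebuilt from
#'   `seed` otherwise).
#' @param seed integer seed (network, tonic input, initial state).
#' @param burn_in_s discarded transient.
#' @param record_neuron as in [simulate_network()].
#' @return An `aqif_sim`; the network's `labels`/`cluster` are attached as
#'   attributes of the result.
#' @export
simulate_clustered <- function(config = clustered_net_config(), duration_s,
                               external_input = NULL, net = NULL, seed = 1L,
                               burn_in_s = 5, record_neuron = 0L) {
  stopifnot(inherits(config, "clustered_net_config"), duration_s > 0)
  if (is.null(net)) net <- build_clustered_network(config, seed)
  n <- config$n_neurons
  base <- model_params()   # shared threshold/reset/reversal constants
  b <- draw_tonic_input(n, config$b0, config$b1, seed + 1L)$b
  set.seed(seed + 2L)
  init <- list(V = stats::runif(n, base$E_L, base$V_reset),
               gE = numeric(n), gI = numeric(n), gA = numeric(n),
               gI_glob = 0)
  ext <- resolve_external_input(external_input, n)
  n_steps <- as.integer(round((duration_s + burn_in_s) * 1000 / config$dt))
  J_E <- methods::as(methods::as(net$J_E, "CsparseMatrix"), "generalMatrix")
  J_I <- methods::as(methods::as(net$J_I, "CsparseMatrix"), "generalMatrix")
  tau_m <- ifelse(net$labels == "E", config$tau_m_E, config$tau_m_I)
  w_a <- ifelse(net$labels == "E", config$wA, 0)

  res <- simulate_core_cpp(
    n_steps, config$dt, tau_m, config$tau_E, config$tau_I, config$tau_A,
    base$E_L, base$V_th, base$V_reset, base$E_E, base$E_I, base$E_A,
    J_E@p, J_E@i, J_E@x, J_I@p, J_I@i, J_I@x,
    0, 0, w_a, b, ext, 0, 0, 0,
    init$V, init$gE, init$gI, init$gA, init$gI_glob,
    integer(0), integer(0), as.integer(record_neuron))

  out <- finish_sim(res, config$dt, n, duration_s, burn_in_s, NULL)
  attr(out, "labels") <- net$labels
  attr(out, "cluster") <- net$cluster
  out
}
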