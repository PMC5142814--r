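#' Build the external input drive from frequency-grouped PSTHs
#'
#' Each model neuron is assigned to one preferred-frequency group
#' (contiguous equal-size tonotopic blocks) and driven by the summed
#' trial-averaged PSTHs of `sources_per_neuron` randomly chosen source
#' channels from that group. The summed drive is then affinely rescaled
#' (gain and offset, clipped at zero) so that its global mean and maximum
#' hit the stated targets; a pure gain cannot satisfy both in general.
#'
#' @param ic an `aqif_ic` object ([gen_ic_psths()]) or a list with `rates`
#'   (channel x time matrix of non-negative rates), `group` (integer group
#'   label per channel) and `dt_ms`.
#' @param n_neurons number of model neurons driven.
#' @param sources_per_neuron source channels summed per neuron (drawn with
#'   replacement if the group has fewer channels).
#' @param rescale `c(mean, max)` targets of the rescaled drive; the
#'   defaults make the peak three times the typical tonic input.
#' @param seed integer seed for the channel draw.
#' @param dt_ms output time step; the PSTHs are linearly interpolated if
#'   their step differs.
#' @param channel_map optional list (length `n_neurons`) of fixed source
#'   channels per neuron, e.g. to reuse one wiring across tone stimuli.
#' @param rescale_map optional `c(gain, offset)` to apply instead of
#'   fitting the affine map (again for reuse across stimuli).
#' @return Object of class `aqif_external_input`: list with `drive`
#'   (`n_neurons` x time matrix), `channel_map`, `group_of_neuron`,
#'   `rescale_map`, `dt_ms`, `seed`.
#' @export
build_external_input <- function(ic, n_neurons, sources_per_neuron = 10L,
                                 rescale = c(mean = 0.06, max = 0.32),
                                 seed = 1L, dt_ms = 0.75,
                                 channel_map = NULL, rescale_map = NULL) {
  rates <- ic$rates
  group <- ic$group
  stopifnot(is.matrix(rates), length(group) == nrow(rates),
            all(rates >= 0))
  if (all(rates == 0)) stop("degenerate input: all PSTHs are zero")
  if (!is.null(ic$dt_ms) && abs(ic$dt_ms - dt_ms) > 1e-9) {
    t_in <- (seq_len(ncol(rates)) - 1) * ic$dt_ms
    t_out <- seq(0, max(t_in), by = dt_ms)
    rates <- t(apply(rates, 1, function(r)
      stats::approx(t_in, r, xout = t_out, rule = 2)$y))
  }
  groups <- sort(unique(group))
  # contiguous equal-size tonotopic blocks of model neurons
  group_of_neuron <- groups[ceiling(seq_len(n_neurons) * length(groups) /
                                      n_neurons)]
  if (is.null(channel_map)) {
    set.seed(seed)
    channel_map <- lapply(group_of_neuron, function(g) {
      ch <- which(group == g)
      sample(ch, sources_per_neuron, replace = length(ch) < sources_per_neuron)
    })
  }
  drive <- t(vapply(channel_map, function(ch)
    colSums(rates[ch, , drop = FALSE]), numeric(ncol(rates))))
  if (is.null(rescale_map))
    rescale_map <- fit_affine_rescale(drive, rescale[[1]], rescale[[2]])
  drive <- pmax(rescale_map[[1]] * drive + rescale_map[[2]], 0)
  structure(list(drive = drive, channel_map = channel_map,
                 group_of_neuron = group_of_neuron,
                 rescale_map = rescale_map, dt_ms = dt_ms, seed = seed),
            class = "aqif_external_input")
}

# gain/offset of max(a x + o, 0) hitting the target mean and max exactly:
# the max pins o = max_target - a * max(x); the clipped mean is then
# continuous and strictly decreasing in a, so the gain is found by
# root-finding
fit_affine_rescale <- function(x, mean_target, max_target) {
  xmax <- max(x)
  xmean <- mean(x)
  if (xmax - xmean < 1e-12 * max(1, xmax))
    stop("infeasible rescale: drive is constant, mean and max targets ",
         "cannot both be met")
  if (mean_target >= max_target)
    stop("infeasible rescale: mean target must be below max target")
  mean_at <- function(a) mean(pmax(a * (x - xmax) + max_target, 0))
  a_hi <- 1
  while (mean_at(a_hi) > mean_target && a_hi < 1e12) a_hi <- a_hi * 2
  r <- stats::uniroot(function(a) mean_at(a) - mean_target,
                      lower = 0, upper = a_hi, tol = 1e-14)
  a <- r$root
  c(gain = a, offset = max_target - a * xmax)
}

#' Simulate evoked responses to a repeated stimulus
#'
#' Keeps the model parameters fixed (at the values fit to spontaneous
#' activity) and drives the network with repeated presentations of the
#' stimulus. Trials are consecutive repetitions within one continuous
#' deterministic simulation, so each presentation meets the network in a
#' different state of its ongoing activity and trial-to-trial variability
#' is entirely intrinsic. An independent-initial-state mode is available.
#'
#' @param params an [model_params()] object (e.g. `fit$best_params`).
#' @param input an [build_external_input()] result; one presentation spans
#'   the input's duration.
#' @param n_trials number of repeated presentations.
#' @param J,b connectivity and tonic input as in [simulate_network()].
#' @param seed integer seed.
#' @param mode `"continuous"` (one session, default) or `"independent"`
#'   (each trial from a fresh seeded initial state).
#' @param bin_ms analysis bin width.
#' @param burn_in_s spontaneous burn-in before the first presentation.
#' @return Object of class `aqif_evoked`: list with `counts` (array
#'   `trial x neuron x bin`), `bin_ms`, `trial_dur_ms`, `params`.
#' @export
simulate_evoked <- function(params, input, n_trials = 330L, J = NULL,
                            b = NULL, seed = 1L,
                            mode = c("continuous", "independent"),
                            bin_ms = 15, burn_in_s = 5) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "aqif_params"),
            inherits(input, "aqif_external_input"), n_trials >= 1)
  drive <- input$drive
  stopifnot(nrow(drive) == params$N)
  trial_dur_ms <- ncol(drive) * input$dt_ms
  bins_per_trial <- as.integer(floor(trial_dur_ms / bin_ms))
  stopifnot(bins_per_trial >= 1)
  n <- params$N
  counts <- array(0L, dim = c(n_trials, n, bins_per_trial))
  if (mode == "continuous") {
    warm <- simulate_network(params, J = J, b = b,
                             duration_s = max(burn_in_s, 0.5),
                             burn_in_s = 0, seed = seed)
    sim <- simulate_network(params, J = J, b = b,
                            duration_s = n_trials * trial_dur_ms / 1000,
                            external_input = drive, init = warm$final,
                            burn_in_s = 0, seed = seed)
    tr <- pmin(n_trials, as.integer(sim$spikes$time_ms %/% trial_dur_ms) + 1L)
    within_ms <- sim$spikes$time_ms - (tr - 1) * trial_dur_ms
    bn <- as.integer(within_ms %/% bin_ms) + 1L
    ok <- bn <= bins_per_trial
    lin <- tr[ok] + n_trials * (sim$spikes$neuron[ok] - 1L) +
      as.double(n_trials) * n * (bn[ok] - 1L)
    counts[] <- tabulate(lin, nbins = n_trials * n * bins_per_trial)
  } else {
    for (t in seq_len(n_trials)) {
      sim <- simulate_network(params, J = J, b = b,
                              duration_s = trial_dur_ms / 1000,
                              external_input = drive,
                              burn_in_s = burn_in_s, seed = seed + 1000L * t)
      r <- bin_raster(sim, bin_ms)
      counts[t, , ] <- r$counts[, seq_len(bins_per_trial)]
    }
  }
  structure(list(counts = counts, bin_ms = bin_ms,
                 trial_dur_ms = trial_dur_ms, params = params),
            class = "aqif_evoked")
}

#' Evoked noise correlations
#'
#' Residual correlations left after subtracting each neuron's mean
#' response to the stimulus across trials; delegates to
#' [noise_correlations()].
#'
#' @param resp an [simulate_evoked()] result or a `trial x neuron x bin`
#'   array.
#' @param neurons optional neuron subset (e.g. a random 50).
#' @param ... passed to [noise_correlations()].
#' @return A `noise_corr` object.
#' @export
evoked_noise_correlations <- function(resp, neurons = NULL, ...) {
  a <- if (inherits(resp, "aqif_evoked")) resp$counts else resp
  if (!is.null(neurons)) a <- a[, neurons, , drop = FALSE]
  noise_correlations(a, method = "residual", ...)
}

#' Full width at half maximum by linear interpolation
#'
#' @param y response values over equally spaced stimuli.
#' @param x stimulus positions (default unit steps).
#' @return Width in `x` units, or `NA` for a flat curve. Curves that do
#'   not fall below half maximum within the sampled range are censored at
#'   the range edge.
#' @export
fwhm <- function(y, x = seq_along(y)) {
  if (max(y) <= min(y)) return(NA_real_)
  half <- max(y) / 2
  pk <- which.max(y)
  left <- x[1]
  if (pk > 1) for (i in pk:2) {
    if (y[i - 1] < half) {
      left <- x[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) *
        (x[i] - x[i - 1])
      break
    }
  }
  right <- x[length(x)]
  if (pk < length(y)) for (i in pk:(length(y) - 1)) {
    if (y[i + 1] < half) {
      right <- x[i] + (y[i] - half) / (y[i] - y[i + 1]) * (x[i + 1] - x[i])
      break
    }
  }
  right - left
}

#' Frequency tuning curves and widths of the driven network
#'
#' Drives the network with the responses of the source population to
#' single tones (one input set per tone, sharing one wiring and one affine
#' rescale fitted to the pooled drive), measures each neuron's mean evoked
#' rate per tone, and reports the full width at half maximum of each
#' neuron's tuning curve in tone steps.
#'
#' @param params an [model_params()] object.
#' @param tone_ic list of `aqif_ic` objects, one per tone (see
#'   [gen_ic_psths()] tone mode).
#' @param n_trials presentations per tone.
#' @param J,b,seed as in [simulate_evoked()].
#' @param ... passed to [simulate_evoked()].
#' @return List of class `aqif_tuning`: `curves` (neuron x tone mean
#'   rates), `widths` (per neuron, `NA` when flat), `mean_width`
#'   (population mean over defined widths), `n_flat`.
#' @export
tuning_width <- function(params, tone_ic, n_trials = 10L, J = NULL, b = NULL,
                         seed = 1L, ...) {
  stopifnot(length(tone_ic) >= 5)
  n <- params$N
  # one wiring for all tones, one affine map fitted on the pooled drive
  first <- build_external_input(tone_ic[[1]], n, seed = seed,
                                rescale_map = c(gain = 1, offset = 0))
  raw <- lapply(tone_ic, function(ic)
    build_external_input(ic, n, seed = seed, channel_map = first$channel_map,
                         rescale_map = c(gain = 1, offset = 0)))
  pooled <- do.call(cbind, lapply(raw, `[[`, "drive"))
  map <- fit_affine_rescale(pooled, 0.06, 0.32)
  curves <- vapply(raw, function(inp) {
    inp$drive <- pmax(map[[1]] * inp$drive + map[[2]], 0)
    resp <- simulate_evoked(params, inp, n_trials = n_trials, J = J, b = b,
                            seed = seed, ...)
    rowMeans(apply(resp$counts, c(2, 3), mean)) /
      (resp$bin_ms / 1000)                      # spikes/s per neuron
  }, numeric(n))
  widths <- apply(curves, 1, fwhm)
  structure(list(curves = curves, widths = widths,
                 mean_width = mean(widths, na.rm = TRUE),
                 n_flat = sum(is.na(widths))),
            class = "aqif_tuning")
}

#' Poisson-likelihood decoder of stimulus tokens
#'
#' A linear-discriminant-style classifier in which the Gaussian noise term
#' is replaced by Poisson likelihoods: the response of each neuron in each
#' 15 ms bin of each token is modelled as Poisson with the
#' empirically-observed training mean, and a test trial is assigned the
#' token with the highest summed log-likelihood. Rates are floored at
#' `1 / (2 * n_train)` so unseen counts keep finite likelihood.
#'
#' @param responses list (one element per token) of `trial x neuron x bin`
#'   count arrays with identical neuron/bin dimensions.
#' @return Object of class `poisson_decoder` with `lambda`
#'   (`token x neuron x bin` rates) and `rate_floor`.
#' @export
train_decoder <- function(responses) {
  stopifnot(length(responses) >= 2,
            all(vapply(responses, function(a) length(dim(a)) == 3,
                       logical(1))))
  n_train <- min(vapply(responses, function(a) dim(a)[1], integer(1)))
  if (n_train < 1) stop("invalid argument: empty training set")
  floor_rate <- 1 / (2 * n_train)
  lam <- vapply(responses, function(a) pmax(apply(a, c(2, 3), mean),
                                            floor_rate),
                matrix(0, dim(responses[[1]])[2], dim(responses[[1]])[3]))
  lam <- aperm(lam, c(3, 1, 2))
  structure(list(lambda = lam, rate_floor = floor_rate),
            class = "poisson_decoder")
}

#' @rdname train_decoder
#' @param model a trained `poisson_decoder`.
#' @param trial a `neuron x bin` count matrix.
#' @return `decode` returns the 1-based index of the most likely token.
#' @export
decode <- function(model, trial) {
  ll <- vapply(seq_len(dim(model$lambda)[1]), function(k) {
    lam <- model$lambda[k, , ]
    sum(trial * log(lam) - lam - lgamma(trial + 1))
  }, numeric(1))
  which.max(ll)
}

#' @rdname train_decoder
#' @param responses_test list per token of held-out `trial x neuron x bin`
#'   arrays.
#' @return `decoding_error` returns the percent of misclassified trials.
#' @export
decoding_error <- function(model, responses_test) {
  n_tot <- 0L; n_err <- 0L
  for (k in seq_along(responses_test)) {
    a <- responses_test[[k]]
    for (t in seq_len(dim(a)[1])) {
      n_tot <- n_tot + 1L
      if (decode(model, a[t, , ]) != k) n_err <- n_err + 1L
    }
  }
  100 * n_err / n_tot
}

#' Cross-validated decoding error
#'
#' Stratified k-fold cross-validation: within each token the trials are
#' partitioned into folds, the decoder is trained on the remaining folds
#' and scored on the held-out one.
#'
#' @param responses list per token of `trial x neuron x bin` arrays.
#' @param folds number of folds.
#' @param seed seed for the fold assignment.
#' @return Mean percent error across folds.
#' @export
decoding_error_cv <- function(responses, folds = 5L, seed = 1L) {
  set.seed(seed)
  assign <- lapply(responses, function(a)
    sample(rep_len(seq_len(folds), dim(a)[1])))
  errs <- vapply(seq_len(folds), function(f) {
    train <- Map(function(a, g) a[g != f, , , drop = FALSE], responses, assign)
    test <- Map(function(a, g) a[g == f, , , drop = FALSE], responses, assign)
    if (any(vapply(test, function(a) dim(a)[1] == 0, logical(1))))
      return(NA_real_)
    decoding_error(train_decoder(train), test)
  }, numeric(1))
  mean(errs, na.rm = TRUE)
}
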