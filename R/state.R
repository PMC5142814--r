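#' Classify fast-spiking and regular-spiking neurons from spike waveforms
#'
#' The mean waveform of each unit is smoothed with a Gaussian kernel of
#' sigma = 0.5 samples (truncated at +/- 4 sigma), the trough is the global
#' minimum and the peak the first subsequent local maximum, and the
#' trough-to-peak time is compared against regime-specific thresholds:
#' awake, FS if `tau < 0.6` ms and RS if `tau > 0.8` ms; anesthetized
#' (conservative, the bimodal distribution lacks a clean separation), FS if
#' `tau < 0.4` ms and RS if `tau > 0.65` ms. Values at or between the
#' thresholds are left unclassified, as are waveforms with no peak after
#' the trough.
#'
#' @param waveforms neuron x sample matrix of mean spike waveforms.
#' @param fs_hz waveform sampling rate (Hz).
#' @param regime `"awake"` or `"anesthetized"`.
#' @return Data frame with `neuron`, `trough_to_peak_ms`, `label`
#'   (`"FS"`, `"RS"` or `"unclassified"`).
#' @export
classify_waveforms <- function(waveforms, fs_hz,
                               regime = c("awake", "anesthetized")) {
  regime <- match.arg(regime)
  waveforms <- as.matrix(waveforms)
  stopifnot(ncol(waveforms) >= 5, fs_hz > 0)
  thr <- if (regime == "awake") c(fs = 0.6, rs = 0.8) else c(fs = 0.4,
                                                             rs = 0.65)
  kern <- stats::dnorm(-2:2, sd = 0.5)
  kern <- kern / sum(kern)
  out <- lapply(seq_len(nrow(waveforms)), function(i) {
    w <- as.numeric(stats::filter(waveforms[i, ], kern, sides = 2))
    ok <- !is.na(w)
    w <- w[ok]
    off <- which(ok)[1] - 1L
    tr <- which.min(w)
    tau <- NA_real_
    if (tr < length(w)) {
      seg <- w[tr:length(w)]
      # first subsequent local maximum (or the end of a rising segment)
      pk <- NA_integer_
      for (k in 2:length(seg)) {
        if ((k == length(seg) && seg[k] > seg[k - 1]) ||
            (k < length(seg) && seg[k] > seg[k - 1] && seg[k] >= seg[k + 1])) {
          pk <- k; break
        }
      }
      if (!is.na(pk)) tau <- (pk - 1) / fs_hz * 1000
    }
    label <- if (is.na(tau)) "unclassified"
    else if (tau < thr[["fs"]]) "FS"
    else if (tau > thr[["rs"]]) "RS"
    else "unclassified"
    data.frame(neuron = i, trough_to_peak_ms = tau, label = label)
  })
  do.call(rbind, out)
}

#' LFP spectrogram with adaptive time-frequency resolution
#'
#' Filters the LFP with Hamming-windowed sine and cosine (quadrature)
#' waves; power is the sum of the two squared filter outputs. The window
#' spans two full periods of the evaluated frequency, clipped to at most
#' one period of 1 Hz at the low end and at least two periods of 30 Hz at
#' the high end. Frequencies are evaluated on an integer-Hz grid.
#'
#' @param lfp numeric voltage trace (already low-pass filtered at 300 Hz
#'   when coming from a wide-band signal).
#' @param fs_hz sampling rate.
#' @param freqs_hz frequencies evaluated (default 1-100 Hz).
#' @param step_s spacing of evaluation times.
#' @return List of class `lfp_spectrogram` with `power`
#'   (frequency x time), `freqs_hz`, `times_s`.
#' @export
lfp_spectrogram <- function(lfp, fs_hz, freqs_hz = 1:100, step_s = 0.05) {
  stopifnot(fs_hz > 2 * max(freqs_hz))
  lfp <- as.numeric(lfp)
  max_win <- max(vapply(freqs_hz, spec_win_s, numeric(1)))
  if (length(lfp) / fs_hz <= max_win)
    stop("invalid argument: LFP shorter than the longest analysis window")
  t_eval <- seq(max_win / 2, length(lfp) / fs_hz - max_win / 2, by = step_s)
  power <- matrix(NA_real_, length(freqs_hz), length(t_eval))
  for (fi in seq_along(freqs_hz)) {
    f <- freqs_hz[fi]
    L <- max(3L, as.integer(round(spec_win_s(f) * fs_hz)))
    h <- hamming_win(L)
    tt <- (seq_len(L) - (L + 1) / 2) / fs_hz
    # amplitude normalization: a unit sinusoid at f projects to ~1, so
    # power is window-length independent and comparable across the
    # adaptive-resolution frequency axis
    ks <- h * sin(2 * pi * f * tt) / (sum(h) / 2)
    kc <- h * cos(2 * pi * f * tt) / (sum(h) / 2)
    centers <- as.integer(round(t_eval * fs_hz))
    half <- (L - 1) %/% 2
    seg_idx <- outer(centers - half, 0:(L - 1), "+")
    seg_idx[seg_idx < 1] <- 1
    seg_idx[seg_idx > length(lfp)] <- length(lfp)
    seg <- matrix(lfp[seg_idx], nrow = length(centers))
    power[fi, ] <- (seg %*% ks)^2 + (seg %*% kc)^2
  }
  structure(list(power = power, freqs_hz = freqs_hz, times_s = t_eval),
            class = "lfp_spectrogram")
}

# window length (s): two periods of f, clipped to [2 periods of 30 Hz,
# 1 period of 1 Hz]
spec_win_s <- function(f) min(max(2 / f, 2 / 30), 1)

hamming_win <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' Synchrony index of the LFP
#'
#' Log ratio of low- to high-frequency LFP power. Trial mode integrates
#' power over the 500 ms (configurable) window following each stimulus
#' onset with bands 3-10 Hz versus 11-96 Hz excluding 45-55 Hz (line
#' noise). Urethane mode evaluates sliding 10 s windows with bands 1-10 Hz
#' versus 11-100 Hz. The index is invariant to LFP gain.
#'
#' @param lfp numeric voltage trace.
#' @param fs_hz sampling rate.
#' @param mode `"trial"` or `"urethane_sliding"`.
#' @param onsets_s stimulus onset times (trial mode).
#' @param window_s analysis window after onset (trial mode).
#' @param slide_window_s,slide_step_s sliding-window length and step
#'   (urethane mode).
#' @return List of class `synchrony_trace` with `times_s`, `synchrony`
#'   (log power ratio, `Inf` flagged when the high band is empty), `mode`.
#' @export
synchrony_index <- function(lfp, fs_hz,
                            mode = c("trial", "urethane_sliding"),
                            onsets_s = NULL, window_s = 0.5,
                            slide_window_s = 10, slide_step_s = 1) {
  mode <- match.arg(mode)
  if (mode == "trial") {
    stopifnot(!is.null(onsets_s))
    low <- 3:10
    high <- setdiff(11:96, 45:55)
    spec <- lfp_spectrogram(lfp, fs_hz, freqs_hz = 1:96, step_s = 0.025)
    val <- vapply(onsets_s, function(t0) {
      sel <- spec$times_s >= t0 & spec$times_s < t0 + window_s
      if (!any(sel)) return(NA_real_)
      p <- rowMeans(spec$power[, sel, drop = FALSE])
      log(sum(p[spec$freqs_hz %in% low]) / sum(p[spec$freqs_hz %in% high]))
    }, numeric(1))
    times <- onsets_s
  } else {
    low <- 1:10
    high <- 11:100
    spec <- lfp_spectrogram(lfp, fs_hz, freqs_hz = 1:100, step_s = 0.25)
    starts <- seq(min(spec$times_s),
                  max(spec$times_s) - slide_window_s, by = slide_step_s)
    val <- vapply(starts, function(t0) {
      sel <- spec$times_s >= t0 & spec$times_s < t0 + slide_window_s
      p <- rowMeans(spec$power[, sel, drop = FALSE])
      log(sum(p[spec$freqs_hz %in% low]) / sum(p[spec$freqs_hz %in% high]))
    }, numeric(1))
    times <- starts + slide_window_s / 2
  }
  if (any(is.infinite(val)))
    warning("synchrony index infinite where high-band power is zero")
  structure(list(times_s = times, synchrony = val, mode = mode),
            class = "synchrony_trace")
}

#' Split trials (or windows) by synchrony
#'
#' `"median"` labels the highest 50 percent of synchrony values as
#' `"sync"` and the rest as `"desync"`. `"quintiles"` assigns rank-based
#' fifths (1 = most desynchronized). `"threshold"` (urethane mode) splits a
#' sliding-window trace at its median and discards a guard zone (default
#' +/- 20 s) around every crossing, returning `NA` there.
#'
#' @param x a `synchrony_trace` or numeric vector of synchrony values.
#' @param scheme `"median"`, `"quintiles"` or `"threshold"`.
#' @param guard_s guard zone half-width for the threshold scheme.
#' @return Character (or integer, for quintiles) labels per trial/window.
#' @export
split_trials_by_synchrony <- function(x, scheme = c("median", "quintiles",
                                                    "threshold"),
                                      guard_s = 20) {
  scheme <- match.arg(scheme)
  times <- NULL
  if (inherits(x, "synchrony_trace")) { times <- x$times_s; x <- x$synchrony }
  n <- length(x)
  if (scheme == "median") {
    if (n < 2) stop("invalid argument: need at least 2 trials")
    rk <- rank(x, ties.method = "first")
    ifelse(rk > n / 2, "sync", "desync")
  } else if (scheme == "quintiles") {
    if (n < 5) stop("invalid argument: need at least 5 trials")
    rk <- rank(x, ties.method = "first")
    as.integer(ceiling(5 * rk / n))
  } else {
    if (is.null(times)) times <- seq_along(x)
    med <- stats::median(x)
    lab <- ifelse(x > med, "sync", "desync")
    cross <- which(lab[-1] != lab[-n]) # boundary between i and i+1
    drop <- rep(FALSE, n)
    for (ci in cross) {
      t0 <- (times[ci] + times[ci + 1]) / 2
      drop <- drop | abs(times - t0) < guard_s
    }
    lab[drop] <- NA
    lab
  }
}

#' Segment a running-speed trace into stationary and running bouts
#'
#' The raw treadmill speed is median-filtered with a 0.5 s window, values
#' below one hundredth of the trace's standard deviation are zeroed as
#' noise, maximal uniform runs (all zero or all nonzero) of at least
#' `min_s` seconds are kept, and one second is trimmed from each end of
#' every segment as a transition period.
#'
#' @param speed numeric non-negative speed trace.
#' @param fs_hz sampling rate.
#' @param min_s minimum segment length before trimming.
#' @param trim_s trimmed from each end.
#' @return Data frame of class `behavior_segments` with `start_s`,
#'   `end_s`, `state` (`"running"` / `"stationary"`), non-overlapping.
#' @export
segment_running <- function(speed, fs_hz, min_s = 5, trim_s = 1) {
  stopifnot(all(speed >= 0), fs_hz > 0)
  k <- max(3L, as.integer(round(0.5 * fs_hz)))
  if (k %% 2 == 0) k <- k + 1L
  sm <- stats::runmed(speed, k)
  sm[sm < stats::sd(speed) / 100] <- 0
  state <- sm > 0
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  keep <- r$lengths >= min_s * fs_hz
  out <- data.frame(
    start_s = (starts[keep] - 1) / fs_hz + trim_s,
    end_s = ends[keep] / fs_hz - trim_s,
    state = ifelse(r$values[keep], "running", "stationary"))
  out <- out[out$end_s > out$start_s, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("behavior_segments", "data.frame")
  out
}

#' Remove evoked responses and equalize firing rates
#'
#' For recordings with repeated stimuli, computes each neuron's mean
#' evoked response to each stimulus (trial mean minus the neuron's
#' spontaneous rate), subtracts it from every trial, excludes units below
#' 0.1 spikes/s, and normalizes the residual rates so every neuron's mean
#' equals the population mean rate. The result isolates the intrinsic
#' population dynamics and feeds the transition refits.
#'
#' @param raster a [spike_raster()] at 15 ms bins.
#' @param onsets_s stimulus onset times (s).
#' @param stim_ids stimulus identity per onset (default: all the same).
#' @param trial_window_s response window per presentation.
#' @param spont_rate_hz per-neuron spontaneous rates; estimated from bins
#'   outside all trial windows when `NULL`.
#' @param min_rate_hz inclusion threshold.
#' @return A raster-like object (class `spike_raster`, signed values) with
#'   attributes `kept_neurons` and `mean_rate_hz`.
#' @export
remove_evoked_and_normalize <- function(raster, onsets_s,
                                        stim_ids = rep(1L, length(onsets_s)),
                                        trial_window_s = 0.5,
                                        spont_rate_hz = NULL,
                                        min_rate_hz = 0.1) {
  stopifnot(inherits(raster, "spike_raster"),
            length(stim_ids) == length(onsets_s))
  if (min(table(stim_ids)) < 2)
    stop("invalid argument: need at least 2 trials per stimulus")
  x <- raster$counts * 1.0
  bin_s <- raster$bin_ms / 1000
  n_bins <- ncol(x)
  wb <- as.integer(round(trial_window_s / bin_s))
  onset_bin <- as.integer(floor(onsets_s / bin_s)) + 1L
  in_trial <- rep(FALSE, n_bins)
  for (ob in onset_bin) in_trial[ob:min(n_bins, ob + wb - 1L)] <- TRUE
  rates <- rowSums(x) / (n_bins * bin_s)
  if (is.null(spont_rate_hz))
    spont_rate_hz <- if (any(!in_trial))
      rowSums(x[, !in_trial, drop = FALSE]) / (sum(!in_trial) * bin_s)
    else rates
  for (sid in unique(stim_ids)) {
    obs <- onset_bin[stim_ids == sid]
    obs <- obs[obs + wb - 1L <= n_bins]
    seg <- vapply(obs, function(ob) x[, ob:(ob + wb - 1L), drop = FALSE],
                  matrix(0, nrow(x), wb))
    evoked <- apply(seg, c(1, 2), mean) - spont_rate_hz * bin_s
    for (ob in obs) x[, ob:(ob + wb - 1L)] <- x[, ob:(ob + wb - 1L)] - evoked
  }
  keep <- which(rates >= min_rate_hz)
  x <- x[keep, , drop = FALSE]
  mean_rate <- mean(rates[keep])
  x <- x * (mean_rate / rates[keep])
  out <- structure(list(counts = x, bin_ms = raster$bin_ms,
                        n_neurons = nrow(x),
                        duration_s = n_bins * bin_s),
                   class = "spike_raster")
  attr(out, "kept_neurons") <- keep
  attr(out, "mean_rate_hz") <- mean_rate
  out
}
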