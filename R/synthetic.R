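#' Surrogate population recording with up/down-state structure
#'
#' A doubly-stochastic stand-in for an in vivo population recording: a
#' two-state (up/down) semi-Markov process with gamma-distributed dwell
#' times modulates per-neuron Poisson rates, optionally multiplied by a
#' slowly varying gain shared by all neurons. Dwell times control the MUA
#' autocorrelation timescale, the down-state rate and occupancy control
#' percent silence, and the shared gain controls mean pairwise
#' correlations -- so cohorts spanning the range of real recordings
#' (rates ~0.5-10 spikes/s, correlations ~0-0.3, silence ~0-80 percent)
#' can be generated with known ground truth.
#'
#' @param n_neurons number of units (default 50, the typical recording
#'   size).
#' @param duration_s recording length.
#' @param up_rate_hz,down_rate_hz per-neuron mean rates in the two states
#'   (scalars or length-`n_neurons` vectors).
#' @param mean_up_ms,mean_down_ms mean dwell times.
#' @param dwell_shape gamma shape of the dwell distribution (1 =
#'   exponential/Markov; larger = more regular alternation).
#' @param shared_gain_sd SD of the log of a shared multiplicative gain
#'   (AR(1) with coefficient `gain_ar` per bin); 0 disables it.
#' @param gain_ar autocorrelation of the shared log-gain per bin.
#' @param bin_ms bin width of the returned raster.
#' @param seed integer seed.
#' @return List of class `aqif_surrogate` with `raster` (a
#'   [spike_raster()]), `state` (1 = up per bin), `gain` (per bin) and the
#'   generating arguments in `spec`.
#' @export
gen_surrogate_recording <- function(n_neurons = 50L, duration_s = 120,
                                    up_rate_hz = 8, down_rate_hz = 0.2,
                                    mean_up_ms = 300, mean_down_ms = 300,
                                    dwell_shape = 2, shared_gain_sd = 0,
                                    gain_ar = 0.95, bin_ms = 15, seed = 1L) {
  stopifnot(all(up_rate_hz >= 0), all(down_rate_hz >= 0),
            mean_up_ms > 0, mean_down_ms > 0, duration_s > 0,
            shared_gain_sd >= 0)
  set.seed(seed)
  n_bins <- as.integer(floor(duration_s * 1000 / bin_ms))
  # alternating gamma dwells, discretized to bins
  total <- 0
  states <- integer(0)
  up <- stats::runif(1) < 0.5
  while (total < n_bins) {
    mean_ms <- if (up) mean_up_ms else mean_down_ms
    d <- max(1L, as.integer(round(
      stats::rgamma(1, shape = dwell_shape,
                    scale = mean_ms / dwell_shape) / bin_ms)))
    states <- c(states, rep(as.integer(up), d))
    total <- total + d
    up <- !up
  }
  states <- states[seq_len(n_bins)]
  gain <- rep(1, n_bins)
  if (shared_gain_sd > 0) {
    z <- as.numeric(stats::arima.sim(list(ar = gain_ar), n_bins,
                                     sd = sqrt(1 - gain_ar^2)))
    gain <- exp(shared_gain_sd * z - shared_gain_sd^2 / 2)
  }
  up_rate_hz <- rep_len(up_rate_hz, n_neurons)
  down_rate_hz <- rep_len(down_rate_hz, n_neurons)
  rate <- outer(up_rate_hz, gain * states) +
    outer(down_rate_hz, gain * (1 - states))
  counts <- matrix(stats::rpois(length(rate), rate * bin_ms / 1000),
                   nrow = n_neurons)
  structure(list(raster = spike_raster(counts, bin_ms), state = states,
                 gain = gain,
                 spec = list(n_neurons = n_neurons, duration_s = duration_s,
                             up_rate_hz = up_rate_hz,
                             down_rate_hz = down_rate_hz,
                             mean_up_ms = mean_up_ms,
                             mean_down_ms = mean_down_ms,
                             dwell_shape = dwell_shape,
                             shared_gain_sd = shared_gain_sd, seed = seed)),
            class = "aqif_surrogate")
}

#' Synthetic cohort of surrogate recordings
#'
#' Draws a cohort whose summary statistics span the ranges seen across
#' real recordings, for use as the normalizing collection of the fit
#' engine.
#'
#' @param n_recordings cohort size (at least 8 recommended).
#' @param duration_s length of each recording.
#' @param seed integer seed.
#' @param ... overrides passed to [gen_surrogate_recording()].
#' @return List of `aqif_surrogate` objects.
#' @export
gen_surrogate_cohort <- function(n_recordings = 8L, duration_s = 120,
                                 seed = 1L, ...) {
  set.seed(seed)
  up <- stats::runif(n_recordings, 2, 12)
  down <- stats::runif(n_recordings, 0, 1)
  dwell_up <- stats::runif(n_recordings, 150, 1500)
  dwell_down <- stats::runif(n_recordings, 80, 800)
  gsd <- stats::runif(n_recordings, 0, 0.6)
  lapply(seq_len(n_recordings), function(i)
    gen_surrogate_recording(duration_s = duration_s, up_rate_hz = up[i],
                            down_rate_hz = down[i], mean_up_ms = dwell_up[i],
                            mean_down_ms = dwell_down[i],
                            shared_gain_sd = gsd[i],
                            seed = seed + 101L * i, ...))
}

#' Synthetic frequency-grouped source PSTHs
#'
#' Emulates trial-averaged responses of a tonotopically organized
#' subcortical source population (channels binned by preferred frequency)
#' for driving the model network. In `"speech"` mode every group responds
#' to a shared amplitude-modulated envelope with group-specific temporal
#' detail; in `"tone"` mode one PSTH set is produced per pure tone, with
#' Gaussian tuning over log-frequency so that a group's response falls off
#' with its distance (in octaves) from the tone.
#'
#' @param n_groups number of preferred-frequency groups.
#' @param channels_per_group source channels per group.
#' @param mode `"speech"` or `"tone"`.
#' @param duration_s stimulus duration per presentation.
#' @param dt_ms PSTH time step.
#' @param peak_rate_hz typical peak source rate.
#' @param tuning_width_oct Gaussian tuning width (SD, octaves) in tone
#'   mode.
#' @param freq_lo_hz,freq_hi_hz frequency range spanned by the groups;
#'   tones are placed at the group centers.
#' @param baseline_hz small stationary background rate.
#' @param seed integer seed.
#' @return In speech mode, an object of class `aqif_ic` (fields `rates`,
#'   `group`, `dt_ms`, `n_groups`, `centers_oct`). In tone mode a list of
#'   class `aqif_ic_tones`: `tones` (list of `aqif_ic`, one per tone) and
#'   `tone_freqs_hz`.
#' @export
gen_ic_psths <- function(n_groups = 8L, channels_per_group = 12L,
                         mode = c("speech", "tone"), duration_s = 1.5,
                         dt_ms = 0.75, peak_rate_hz = 100,
                         tuning_width_oct = 0.5, freq_lo_hz = 256,
                         freq_hi_hz = 8192, baseline_hz = 1, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_groups >= 1, channels_per_group >= 1, duration_s > 0,
            peak_rate_hz >= 0)
  set.seed(seed)
  n_t <- as.integer(round(duration_s * 1000 / dt_ms))
  centers_oct <- seq(log2(freq_lo_hz), log2(freq_hi_hz),
                     length.out = n_groups)
  group <- rep(seq_len(n_groups), each = channels_per_group)
  smooth_env <- function(tc_ms) {
    e <- stats::filter(stats::rnorm(n_t)^2, rep(1, max(1, round(tc_ms / dt_ms))),
                       circular = TRUE)
    e <- as.numeric(e)
    pmax(e - stats::quantile(e, 0.3), 0) / max(e)
  }
  if (mode == "speech") {
    global_env <- smooth_env(120)   # syllabic-rate amplitude modulation
    rates <- matrix(0, n_groups * channels_per_group, n_t)
    for (g in seq_len(n_groups)) {
      # each frequency band follows its own formant-like modulation, with
      # a modest shared syllabic component
      genv <- 0.25 * global_env + 0.75 * smooth_env(60)
      for (ch in which(group == g)) {
        gain <- stats::runif(1, 0.5, 1.5)
        rates[ch, ] <- baseline_hz +
          peak_rate_hz * gain * genv * stats::runif(1, 0.8, 1.2)
      }
    }
    structure(list(rates = rates, group = group, dt_ms = dt_ms,
                   n_groups = n_groups, centers_oct = centers_oct),
              class = "aqif_ic")
  } else {
    # 75 ms tone with onset-weighted envelope, then silence
    tt <- (seq_len(n_t) - 1) * dt_ms
    env <- ifelse(tt < 75, exp(-tt / 50) * (1 - exp(-tt / 5)), 0)
    env <- env / max(env)
    tones <- lapply(seq_len(n_groups), function(tn) {
      rates <- matrix(0, n_groups * channels_per_group, n_t)
      for (g in seq_len(n_groups)) {
        tune <- exp(-(centers_oct[g] - centers_oct[tn])^2 /
                      (2 * tuning_width_oct^2))
        for (ch in which(group == g)) {
          rates[ch, ] <- baseline_hz +
            peak_rate_hz * tune * stats::runif(1, 0.8, 1.2) * env
        }
      }
      structure(list(rates = rates, group = group, dt_ms = dt_ms,
                     n_groups = n_groups, centers_oct = centers_oct),
                class = "aqif_ic")
    })
    structure(list(tones = tones, tone_freqs_hz = 2^centers_oct),
              class = "aqif_ic_tones")
  }
}

#' Synthetic spike waveforms with bimodal trough-to-peak widths
#'
#' Each waveform is a negative Gaussian trough followed by a positive
#' Gaussian peak displaced by the unit's trough-to-peak time, drawn from a
#' two-component mixture (narrow = fast-spiking-like, broad =
#' regular-spiking-like).
#'
#' @param n_neurons number of units.
#' @param frac_narrow fraction drawn from the narrow component.
#' @param narrow_ms,broad_ms component means (trough-to-peak, ms).
#' @param sd_ms within-component SD.
#' @param fs_hz waveform sampling rate.
#' @param span_ms waveform length.
#' @param seed integer seed.
#' @return List with `waveforms` (neuron x sample), `fs_hz`,
#'   `true_label` (`"FS"`/`"RS"`), `trough_to_peak_ms` (planted values).
#' @export
gen_waveforms <- function(n_neurons = 40L, frac_narrow = 0.3,
                          narrow_ms = 0.3, broad_ms = 1.0, sd_ms = 0.05,
                          fs_hz = 2e4, span_ms = 3, seed = 1L) {
  set.seed(seed)
  narrow <- stats::runif(n_neurons) < frac_narrow
  tau <- ifelse(narrow, stats::rnorm(n_neurons, narrow_ms, sd_ms),
                stats::rnorm(n_neurons, broad_ms, sd_ms))
  tau <- pmax(tau, 2 / fs_hz * 1000)
  tt <- seq(0, span_ms, by = 1000 / fs_hz)
  t0 <- span_ms / 4
  wf <- t(vapply(tau, function(tp)
    -exp(-(tt - t0)^2 / (2 * 0.05^2)) +
      0.6 * exp(-(tt - t0 - tp)^2 / (2 * (0.08 + 0.1 * tp)^2)),
    numeric(length(tt))))
  list(waveforms = wf, fs_hz = fs_hz,
       true_label = ifelse(narrow, "FS", "RS"), trough_to_peak_ms = tau)
}

#' Synthetic running-speed trace
#'
#' Alternating stationary and running bouts with smooth speed envelopes.
#'
#' @param duration_s trace length.
#' @param fs_hz sampling rate.
#' @param bout_starts_s,bout_ends_s explicit running bouts; generated
#'   (exponential gaps, ~8 s bouts) when `NULL`.
#' @param speed_cm_s typical running speed.
#' @param noise_sd measurement noise SD.
#' @param seed integer seed.
#' @return List with `speed` (non-negative), `fs_hz`, `bouts` (data frame
#'   `start_s`, `end_s`).
#' @export
gen_speed_trace <- function(duration_s = 120, fs_hz = 100,
                            bout_starts_s = NULL, bout_ends_s = NULL,
                            speed_cm_s = 15, noise_sd = 0.02, seed = 1L) {
  set.seed(seed)
  if (is.null(bout_starts_s)) {
    t <- 5
    bout_starts_s <- c(); bout_ends_s <- c()
    while (t < duration_s - 15) {
      bout_starts_s <- c(bout_starts_s, t)
      len <- stats::runif(1, 6, 12)
      bout_ends_s <- c(bout_ends_s, t + len)
      t <- t + len + stats::runif(1, 8, 20)
    }
  }
  n <- as.integer(duration_s * fs_hz)
  tt <- (seq_len(n) - 1) / fs_hz
  speed <- stats::rnorm(n, 0, noise_sd)
  for (bi in seq_along(bout_starts_s)) {
    sel <- tt >= bout_starts_s[bi] & tt < bout_ends_s[bi]
    ramp <- pmin(1, (tt[sel] - bout_starts_s[bi]) / 0.5,
                 (bout_ends_s[bi] - tt[sel]) / 0.5)
    speed[sel] <- speed[sel] + speed_cm_s * ramp *
      (1 + 0.1 * sin(2 * pi * 1.5 * tt[sel]))
  }
  list(speed = pmax(speed, 0), fs_hz = fs_hz,
       bouts = data.frame(start_s = bout_starts_s, end_s = bout_ends_s))
}

#' Jointly consistent synthetic state cohort
#'
#' Generates a bundle emulating one recording session with cortical-state
#' structure: a slow synchronized/desynchronized state process; a
#' population raster in which synchronized epochs carry up/down-like
#' common fluctuations and fast-spiking units change gain across states; an
#' LFP whose low-frequency power is elevated when synchronized; spike
#' waveforms from the bimodal width mixture consistent with the FS/RS
#' labels; and a running-speed trace whose bouts drive desynchronization.
#'
#' @param n_neurons units in the raster.
#' @param duration_s session length.
#' @param frac_fs fraction of fast-spiking units.
#' @param fs_gain_desync,fs_gain_sync FS rate gain in the two states (the
#'   desync/sync ratio is the planted effect recovered by quintile
#'   analyses).
#' @param rs_rate_hz,fs_rate_hz baseline rates.
#' @param state_period_s mean duration of each state epoch.
#' @param lfp_fs_hz,bin_ms sampling resolutions.
#' @param lfp_low_gain multiplicative low-frequency (4 Hz) LFP amplitude in
#'   the synchronized state relative to desynchronized.
#' @param seed integer seed.
#' @return List of class `aqif_state_cohort`: `raster`, `state` (per bin,
#'   `"sync"`/`"desync"`), `lfp` (list `voltage`, `fs_hz`), `waveforms`
#'   (as [gen_waveforms()]), `speed` (as [gen_speed_trace()]),
#'   `true_label`, and `spec`.
#' @export
gen_state_cohort <- function(n_neurons = 40L, duration_s = 120,
                             frac_fs = 0.3, fs_gain_desync = 4,
                             fs_gain_sync = 1, rs_rate_hz = 4,
                             fs_rate_hz = 6, state_period_s = 20,
                             lfp_fs_hz = 500, bin_ms = 15,
                             lfp_low_gain = 3, seed = 1L) {
  stopifnot(fs_gain_desync > 0, fs_gain_sync > 0)
  set.seed(seed)
  n_bins <- as.integer(floor(duration_s * 1000 / bin_ms))
  # state epochs follow running bouts plus intrinsic alternation
  speed <- gen_speed_trace(duration_s, fs_hz = 100, seed = seed + 1L)
  tt_bin <- (seq_len(n_bins) - 0.5) * bin_ms / 1000
  running <- vapply(tt_bin, function(t)
    any(t >= speed$bouts$start_s & t < speed$bouts$end_s), logical(1))
  intrinsic <- gen_surrogate_recording(
    n_neurons = 1, duration_s = duration_s,
    mean_up_ms = state_period_s * 1000, mean_down_ms = state_period_s * 1000,
    bin_ms = bin_ms, seed = seed + 2L)$state
  sync <- !running & intrinsic == 1L
  state <- ifelse(sync, "sync", "desync")

  wf <- gen_waveforms(n_neurons, frac_narrow = frac_fs, seed = seed + 3L)
  is_fs <- wf$true_label == "FS"
  # synchronized epochs carry a common up/down modulation
  common <- gen_surrogate_recording(n_neurons = 1, duration_s = duration_s,
                                    mean_up_ms = 300, mean_down_ms = 300,
                                    bin_ms = bin_ms, seed = seed + 4L)$state
  mod <- ifelse(sync, ifelse(common == 1L, 1.8, 0.1), 1)
  base <- ifelse(is_fs, fs_rate_hz, rs_rate_hz)
  gain_state <- ifelse(rep(sync, each = n_neurons) & is_fs, fs_gain_sync,
                       ifelse(rep(!sync, each = n_neurons) & is_fs,
                              fs_gain_desync, 1))
  rate <- matrix(base, n_neurons, n_bins) *
    matrix(gain_state, n_neurons, n_bins) *
    matrix(rep(mod, each = n_neurons), n_neurons, n_bins)
  counts <- matrix(stats::rpois(length(rate), rate * bin_ms / 1000),
                   n_neurons, n_bins)

  n_lfp <- as.integer(duration_s * lfp_fs_hz)
  tl <- (seq_len(n_lfp) - 1) / lfp_fs_hz
  sync_l <- sync[pmin(n_bins, floor(tl * 1000 / bin_ms) + 1L)]
  low_amp <- ifelse(sync_l, lfp_low_gain, 1)
  lfp <- low_amp * sin(2 * pi * 4 * tl) +
    0.5 * sin(2 * pi * 30 * tl + stats::runif(1) * 2 * pi) +
    stats::rnorm(n_lfp, 0, 0.5)
  structure(list(raster = spike_raster(counts, bin_ms), state = state,
                 lfp = list(voltage = lfp, fs_hz = lfp_fs_hz),
                 waveforms = wf, speed = speed, true_label = wf$true_label,
                 spec = list(n_neurons = n_neurons, duration_s = duration_s,
                             frac_fs = frac_fs,
                             fs_gain_desync = fs_gain_desync,
                             fs_gain_sync = fs_gain_sync,
                             state_period_s = state_period_s, seed = seed)),
            class = "aqif_state_cohort")
}
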