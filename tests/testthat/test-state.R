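# waveform with an exact trough-to-peak separation (ms) at a given rate
mk_wave <- function(tau_ms, fs_hz = 2e4, span_ms = 3) {
  tt <- seq(0, span_ms, by = 1000 / fs_hz)
  t0 <- span_ms / 4
  -exp(-(tt - t0)^2 / (2 * 0.05^2)) +
    0.6 * exp(-(tt - t0 - tau_ms)^2 / (2 * 0.12^2))
}

test_that("waveform classification follows the regime thresholds exactly", {
  fs <- 2e4
  taus <- c(0.3, 0.5, 0.7, 0.9, 1.2)
  wf <- t(vapply(taus, mk_wave, numeric(length(mk_wave(1)))))
  aw <- classify_waveforms(wf, fs, regime = "awake")
  expect_equal(aw$label, c("FS", "FS", "unclassified", "RS", "RS"))
  an <- classify_waveforms(wf, fs, regime = "anesthetized")
  expect_equal(an$label, c("FS", "unclassified", "RS", "RS", "RS"))
  # measured trough-to-peak close to the planted separation
  expect_true(all(abs(aw$trough_to_peak_ms - taus) < 0.1))
  # order invariance
  aw2 <- classify_waveforms(wf[5:1, ], fs, regime = "awake")
  expect_equal(aw2$label, rev(aw$label))
  # no peak after the trough -> unclassified
  mono <- matrix(seq(0, -1, length.out = 60), 1)
  expect_equal(classify_waveforms(mono, fs)$label, "unclassified")
})

test_that("spectrogram concentrates power at the driving frequency and scales quadratically", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)
  x <- sin(2 * pi * 5 * t)
  sp <- lfp_spectrogram(x, fs, freqs_hz = 1:40, step_s = 0.25)
  pw <- rowMeans(sp$power)
  expect_identical(sp$freqs_hz[which.max(pw)], 5L)
  # the two-period Hamming windows have a main lobe of half-width ~f, so
  # concentration is asserted outside the lobe
  expect_gt(pw[5], 10 * max(pw[sp$freqs_hz >= 15]))
  expect_gt(pw[5], 10 * max(pw[sp$freqs_hz <= 2]))
  sp2 <- lfp_spectrogram(2 * x, fs, freqs_hz = 1:40, step_s = 0.25)
  expect_equal(sp2$power, 4 * sp$power, tolerance = 1e-12)
  expect_error(lfp_spectrogram(x, 50, freqs_hz = 1:40), "fs")
})

test_that("synchrony index signs and gain invariance", {
  fs <- 400
  t <- seq(0, 30, by = 1 / fs)
  set.seed(1)
  low_dom <- sin(2 * pi * 5 * t) + 0.01 * rnorm(length(t))
  high_dom <- sin(2 * pi * 70 * t) + 0.01 * rnorm(length(t))
  s_low <- synchrony_index(low_dom, fs, mode = "trial",
                           onsets_s = c(5, 10, 15), window_s = 0.5)
  s_high <- synchrony_index(high_dom, fs, mode = "trial",
                            onsets_s = c(5, 10, 15), window_s = 0.5)
  expect_true(all(s_low$synchrony > 1.5))
  expect_true(all(s_high$synchrony < 0))
  s_gain <- synchrony_index(7.3 * low_dom, fs, mode = "trial",
                            onsets_s = c(5, 10, 15), window_s = 0.5)
  expect_equal(s_gain$synchrony, s_low$synchrony, tolerance = 1e-9)
})

test_that("state-switching LFP yields higher synchrony in the synchronized half", {
  fs <- 400
  half_s <- 60
  t1 <- seq(0, half_s - 1 / fs, by = 1 / fs)
  for (sd in 1:3) {
    set.seed(sd)
    sync_half <- 2 * sin(2 * pi * 4 * t1) + rnorm(length(t1), 0, 0.7)
    desync_half <- 1 * sin(2 * pi * 4 * t1) + rnorm(length(t1), 0, 0.7)
    lfp <- c(sync_half, desync_half)
    tr <- synchrony_index(lfp, fs, mode = "urethane_sliding")
    first <- tr$synchrony[tr$times_s < half_s - 5]
    second <- tr$synchrony[tr$times_s > half_s + 5]
    expect_gt(median(first), median(second))
  }
})

test_that("synchrony-based trial splits", {
  vals <- c(3, 1, 4, 1.5, 5, 9, 2.6, 0.5, 3.5, 7)
  lab <- split_trials_by_synchrony(vals, "median")
  expect_identical(sum(lab == "sync"), 5L)
  expect_identical(sum(lab == "desync"), 5L)
  expect_true(all(vals[lab == "sync"] >= max(vals[lab == "desync"]) - 1e-12 |
                    rank(vals)[lab == "sync"] > 5))
  q <- split_trials_by_synchrony(sort(runif(20)), "quintiles")
  expect_equal(as.numeric(table(q)), rep(4, 5))
  expect_equal(q, rep(1:5, each = 4))
  expect_error(split_trials_by_synchrony(1, "median"), "invalid")
  expect_error(split_trials_by_synchrony(c(1, 2), "quintiles"), "invalid")
  # urethane threshold: one crossing, 20 s guard discarded on both sides
  times <- seq(5, 204, by = 1)
  set.seed(6)
  x <- c(rnorm(100, 1, 0.05), rnorm(100, -1, 0.05))
  tr <- structure(list(times_s = times, synchrony = x,
                       mode = "urethane_sliding"),
                  class = "synchrony_trace")
  lab <- split_trials_by_synchrony(tr, "threshold", guard_s = 20)
  cross_t <- (times[100] + times[101]) / 2
  expect_true(all(is.na(lab[abs(times - cross_t) < 20])))
  expect_true(all(lab[times < cross_t - 20] == "sync", na.rm = TRUE))
  expect_true(all(lab[times > cross_t + 20] == "desync", na.rm = TRUE))
  expect_identical(sum(is.na(lab)), sum(abs(times - cross_t) < 20))
})

test_that("running segmentation applies the median filter, threshold, minimum and trim rules", {
  fs <- 100
  # constant zero for 20 s -> one stationary segment trimmed to 1-19 s
  seg <- segment_running(rep(0, 20 * fs), fs)
  expect_identical(nrow(seg), 1L)
  expect_equal(seg$state, "stationary")
  expect_equal(seg$start_s, 1)
  expect_equal(seg$end_s, 19)
  # 10 s run inside stillness -> running segment trimmed to 8 s
  sp <- gen_speed_trace(40, fs, bout_starts_s = 15, bout_ends_s = 25,
                        noise_sd = 0, seed = 2)
  seg <- segment_running(sp$speed, fs)
  run <- seg[seg$state == "running", ]
  expect_identical(nrow(run), 1L)
  expect_lt(abs((run$end_s - run$start_s) - 8), 0.3)
  # a 4 s run is below the 5 s minimum
  sp4 <- gen_speed_trace(40, fs, bout_starts_s = 15, bout_ends_s = 19,
                         noise_sd = 0, seed = 3)
  seg4 <- segment_running(sp4$speed, fs)
  expect_identical(sum(seg4$state == "running"), 0L)
})

test_that("evoked-response removal and rate normalization", {
  set.seed(4)
  n_nr <- 10; bin_ms <- 15
  n_bins <- 4000
  onsets <- seq(5, 55, by = 5)
  psth <- matrix(runif(n_nr * 33, 0, 3), n_nr, 33)
  counts <- matrix(rpois(n_nr * n_bins, 1.2), n_nr, n_bins)
  # deterministic identical evoked responses on every trial
  det <- matrix(0, n_nr, n_bins)
  for (o in onsets) {
    ob <- floor(o / 0.015) + 1
    det[, ob:(ob + 32)] <- psth
  }
  r <- spike_raster(counts + det, bin_ms)
  out <- remove_evoked_and_normalize(r, onsets, trial_window_s = 33 * 0.015)
  # residuals in the trial windows no longer carry the evoked structure:
  # the trial-averaged residual is flat where the raw trial average tracks
  # the PSTH
  ob <- floor(onsets / 0.015) + 1
  resid_avg <- Reduce(`+`, lapply(ob, function(o)
    out$counts[, o:(o + 32)])) / length(ob)
  raw_avg <- Reduce(`+`, lapply(ob, function(o)
    (counts + det)[, o:(o + 32)])) / length(ob)
  cor_raw <- cor(as.numeric(raw_avg), as.numeric(psth))
  cor_resid <- cor(as.numeric(resid_avg), as.numeric(psth))
  expect_gt(cor_raw, 0.8)
  expect_lt(abs(cor_resid), 0.3)
  # every kept neuron's mean rate equals the population mean
  rates <- rowMeans(out$counts) / 0.015
  expect_lt(max(abs(rates - mean(rates))) / mean(rates), 0.3)
  expect_error(remove_evoked_and_normalize(r, onsets[1]), "invalid")
})

test_that("planted slow common fluctuation survives evoked-response removal", {
  gen <- gen_surrogate_recording(n_neurons = 30, duration_s = 120,
                                 up_rate_hz = 8, down_rate_hz = 0.5,
                                 mean_up_ms = 600, mean_down_ms = 600,
                                 seed = 5)
  onsets <- seq(2, 118, by = 4)
  out <- remove_evoked_and_normalize(gen$raster, onsets,
                                     trial_window_s = 0.5)
  mua <- colSums(out$counts)
  a <- fit_acf_envelope(mua_acf(structure(mua, bin_ms = 15), 600))
  # dwell-time structure (~600 ms epochs) still dominates the residual ACF
  expect_gt(a$fit[["T_decay"]], 100)
})
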