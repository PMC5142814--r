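test_that("external input hits its mean and max targets exactly", {
  ic <- gen_ic_psths(mode = "speech", duration_s = 0.75, seed = 2)
  inp <- build_external_input(ic, n_neurons = 128, seed = 3)
  expect_lt(abs(mean(inp$drive) - 0.06) / 0.06, 1e-6)
  expect_lt(abs(max(inp$drive) - 0.32) / 0.32, 1e-6)
  expect_true(all(inp$drive >= 0))
  # every neuron draws 10 channels from its own tonotopic group
  expect_true(all(lengths(inp$channel_map) == 10))
  g <- inp$group_of_neuron
  expect_true(all(vapply(seq_along(inp$channel_map), function(i)
    all(ic$group[inp$channel_map[[i]]] == g[i]), logical(1))))
})

test_that("constant PSTHs make the affine rescale infeasible", {
  ic <- list(rates = matrix(1, 8, 100), group = rep(1:2, each = 4),
             dt_ms = 0.75)
  expect_error(build_external_input(ic, n_neurons = 16), "infeasible")
  ic0 <- list(rates = matrix(0, 8, 100), group = rep(1:2, each = 4),
              dt_ms = 0.75)
  expect_error(build_external_input(ic0, n_neurons = 16), "degenerate")
})

test_that("evoked simulation is reproducible and reduces to spontaneous", {
  p <- model_params()
  ic <- gen_ic_psths(mode = "speech", duration_s = 0.6, seed = 4)
  inp <- build_external_input(ic, n_neurons = p$N, seed = 5)
  a <- simulate_evoked(p, inp, n_trials = 5, seed = 6, burn_in_s = 1)
  b <- simulate_evoked(p, inp, n_trials = 5, seed = 6, burn_in_s = 1)
  expect_identical(a$counts, b$counts)
  expect_identical(dim(a$counts), c(5L, 512L, 40L))
  # zero input: the continuous session is the spontaneous trajectory
  inp0 <- inp
  inp0$drive <- inp$drive * 0
  ev0 <- simulate_evoked(p, inp0, n_trials = 5, seed = 6, burn_in_s = 1)
  warm <- simulate_network(p, duration_s = 1, burn_in_s = 0, seed = 6)
  spont <- simulate_network(p, duration_s = 3, burn_in_s = 0, seed = 6,
                            init = warm$final)
  r <- bin_raster(spont, 15)
  tot_by_neuron <- apply(ev0$counts, 2, sum)
  expect_equal(unname(tot_by_neuron), unname(rowSums(r$counts)))
})

test_that("full width at half maximum by linear interpolation", {
  expect_equal(fwhm(c(0, 1, 2, 1, 0)), 2)
  expect_lte(fwhm(c(0, 0, 1, 0, 0)), 1)
  expect_true(is.na(fwhm(c(1, 1, 1))))
  expect_equal(fwhm(c(0, 2, 0)), 1)
  # asymmetric curve: half max 2, crossings at x = 2 and x = 4.5
  expect_equal(fwhm(c(0, 2, 4, 3, 1, 0)), 2.5)
})

test_that("Poisson decoder arithmetic and sanity", {
  # single neuron, single bin: lambda_A = 1, lambda_B = 3, count 2 -> B
  model <- structure(list(lambda = array(c(1, 3), c(2, 1, 1)),
                          rate_floor = 0.01), class = "poisson_decoder")
  expect_identical(decode(model, matrix(2, 1, 1)), 2L)
  expect_identical(decode(model, matrix(0, 1, 1)), 1L)

  # disjoint-support tokens decode perfectly
  set.seed(7)
  n_tok <- 4; n_tr <- 12; n_nr <- 20; n_bin <- 10
  responses <- lapply(1:n_tok, function(k) {
    a <- array(0L, c(n_tr, n_nr, n_bin))
    act <- ((k - 1) * 5 + 1):(k * 5)
    a[, act, ] <- rpois(n_tr * 5 * n_bin, 3)
    a
  })
  expect_equal(decoding_error_cv(responses, folds = 3, seed = 1), 0)

  # shuffled labels decode at chance: 1 - 1/K
  set.seed(8)
  pool <- array(rpois(60 * n_nr * n_bin, 2), c(60, n_nr, n_bin))
  shuffled <- lapply(split(sample(60), rep(1:6, each = 10)), function(ix)
    pool[ix, , , drop = FALSE])
  err <- decoding_error_cv(shuffled, folds = 3, seed = 2)
  chance <- 100 * (1 - 1 / 6)
  se3 <- 3 * 100 * sqrt(1 / 6 * 5 / 6 / 60)
  expect_lt(abs(err - chance), se3 + 5)
})

test_that("evoked noise correlations delegate to the residual estimator", {
  set.seed(9)
  a <- array(rpois(20 * 8 * 12, 2), c(20, 8, 12))
  ev <- structure(list(counts = a, bin_ms = 15), class = "aqif_evoked")
  nc1 <- evoked_noise_correlations(ev)
  nc2 <- noise_correlations(a, method = "residual")
  expect_equal(nc1$c_ij, nc2$c_ij)
  nc3 <- evoked_noise_correlations(ev, neurons = 1:4)
  expect_identical(dim(nc3$c_ij), c(4L, 4L))
})

test_that("tone-driven tuning curves peak at the preferred group and have finite widths", {
  p <- model_params(N = 128L)
  tones <- gen_ic_psths(n_groups = 6, mode = "tone", duration_s = 0.3,
                        seed = 10)
  expect_length(tones$tones, 6)
  tw <- tuning_width(p, tones$tones, n_trials = 4, seed = 11, burn_in_s = 0.5)
  expect_identical(dim(tw$curves), c(128L, 6L))
  expect_true(is.finite(tw$mean_width))
  expect_gt(tw$mean_width, 0)
  # neurons respond more to their own group's tone than to the farthest one
  grp <- rep(1:6, each = ceiling(128 / 6))[1:128]
  own <- tw$curves[cbind(1:128, grp)]
  far <- tw$curves[cbind(1:128, ifelse(grp <= 3, 6L, 1L))]
  expect_gt(mean(own - far, na.rm = TRUE), 0)
})

test_that("stronger inhibition sharpens tuning and improves decoding", {
  p_lo <- model_params(wI = 0.05)
  p_hi <- model_params(wI = 0.40)
  tones <- gen_ic_psths(n_groups = 6, mode = "tone", duration_s = 0.3,
                        seed = 12)
  w_lo <- tuning_width(p_lo, tones$tones, n_trials = 6, seed = 13,
                       burn_in_s = 1)
  w_hi <- tuning_width(p_hi, tones$tones, n_trials = 6, seed = 13,
                       burn_in_s = 1)
  expect_lte(w_hi$mean_width, w_lo$mean_width)

  # seven 0.25 s tokens cut from one speech-like stimulus; the decoding
  # benefit of inhibition is assessed in the moderate-excitation regime
  # where quenched intrinsic variability dominates the rate loss
  ic <- gen_ic_psths(mode = "speech", duration_s = 1.75, seed = 14)
  err_of <- function(p) {
    inp <- build_external_input(ic, p$N, seed = 15)
    seg_len <- ncol(inp$drive) %/% 7
    responses <- lapply(1:7, function(k) {
      tok <- inp
      tok$drive <- inp$drive[, ((k - 1) * seg_len + 1):(k * seg_len)]
      ev <- simulate_evoked(p, tok, n_trials = 30, seed = 16, burn_in_s = 1)
      ev$counts
    })
    decoding_error_cv(responses, folds = 5, seed = 17)
  }
  base <- model_params(wA = 0.55, wE = 3.5, b1 = 0.02, b0 = 0.02)
  d_lo <- base; d_lo$wI <- 0.05
  d_hi <- base; d_hi$wI <- 0.40
  expect_lt(err_of(d_hi), err_of(d_lo))
})
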