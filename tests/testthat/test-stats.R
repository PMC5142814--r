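test_that("MUA is the per-bin population sum and conserves spikes", {
  counts <- matrix(0L, 2, 6)
  counts[1, 3] <- 1L; counts[2, 3] <- 1L; counts[1, 5] <- 2L
  r <- spike_raster(counts, 15)
  mua <- compute_mua(r)
  expect_equal(as.numeric(mua), c(0, 0, 2, 0, 2, 0))
  expect_equal(sum(mua), sum(counts))
  # dt-resolution raster rebinned to 15 ms
  fine <- spike_raster(matrix(1L, 1, 20), 0.75)
  expect_equal(as.numeric(compute_mua(fine, 15)), 20)
  # Poisson raster: mean MUA = n * rate * bin
  r <- poisson_raster(50, 5, 60, seed = 2)
  expect_lt(abs(mean(compute_mua(r)) - 3.75), 3 * sqrt(3.75 / ncol(r$counts)))
  expect_error(compute_mua(spike_raster(matrix(integer(0), 2, 0), 15)),
               "empty")
})

test_that("1 Hz high-pass removes slow components and keeps fast ones", {
  bin_s <- 0.015
  t <- seq(0, 120, by = bin_s)
  slow <- sin(2 * pi * 0.05 * t)
  fast <- sin(2 * pi * 5 * t)
  hp_slow <- highpass_mua(structure(slow, bin_ms = 15))
  hp_fast <- highpass_mua(structure(fast, bin_ms = 15))
  expect_lt(sum(hp_slow^2) / sum(slow^2), 0.01)
  expect_gt(sum(hp_fast^2) / sum(fast^2), 0.8)
  hp_const <- highpass_mua(structure(rep(3, 5000), bin_ms = 15))
  expect_lt(max(abs(hp_const)), 1e-6)
  expect_error(highpass_mua(structure(1:5, bin_ms = 15)), "short")
})

test_that("MUA autocorrelation is normalized and matches the AR(1) oracle", {
  set.seed(7)
  wn <- structure(rnorm(20000), bin_ms = 15)
  a <- mua_acf(wn, max_lag_ms = 300)
  expect_equal(a$acf[1], 1)
  expect_true(all(abs(a$acf[-1]) < 3 / sqrt(20000)))
  # AR(1) with coefficient 0.8 per bin: acf(k) = 0.8^k
  set.seed(8)
  ar <- structure(as.numeric(arima.sim(list(ar = 0.8), 50000)), bin_ms = 15)
  a <- mua_acf(ar, max_lag_ms = 150)
  lags_bins <- a$lags_ms / 15
  expect_true(all(abs(a$acf - 0.8^lags_bins) < 0.05))
  expect_error(mua_acf(structure(rep(2, 1000), bin_ms = 15), 150),
               "degenerate")
  expect_error(mua_acf(wn, max_lag_ms = 20000 * 15), "invalid")
})

test_that("ACF envelope fit recovers planted parameters", {
  lags <- seq(0, 600, by = 15)
  true <- c(a = 1, T = 150, tp = 8)
  y <- true[["a"]] * exp(-lags / true[["T"]]) *
    cos(lags / (2 * pi * true[["tp"]]))
  res <- structure(list(lags_ms = lags, acf = y,
                        fit = c(a = NA, T_decay = NA, t_period = NA)),
                   class = "acf_result")
  fit <- fit_acf_envelope(res)$fit
  expect_lt(abs(fit[["a"]] - 1), 0.01)
  expect_lt(abs(fit[["T_decay"]] - 150) / 150, 0.01)
  expect_lt(abs(fit[["t_period"]] - 8) / 8, 0.01)
  # pure exponential: decay recovered, oscillation on its large/unbounded
  # branch without error
  y2 <- exp(-lags / 120)
  res$acf <- y2
  fit2 <- fit_acf_envelope(res)$fit
  expect_lt(abs(fit2[["T_decay"]] - 120) / 120, 0.02)
  expect_gt(fit2[["t_period"]], 50)
  # degenerate: no correlation beyond lag 0
  res$acf <- c(1, rep(0, length(lags) - 1))
  fit3 <- fit_acf_envelope(res)$fit
  expect_equal(fit3[["T_decay"]], 1)
})

test_that("sorted MUA and percent silence", {
  s <- sorted_mua_and_silence(c(0, 0, 3, 1))
  expect_equal(s$sorted, c(0, 0, 1, 3))
  expect_equal(s$pct_silence, 50)
  expect_equal(sorted_mua_and_silence(rep(0, 7))$pct_silence, 100)
  # Poisson(3) zero mass = exp(-3) ~ 5.0%
  set.seed(3)
  mua <- rpois(50000, 3)
  expect_lt(abs(sorted_mua_and_silence(mua)$pct_silence - 100 * exp(-3)), 0.5)
})

test_that("mean pairwise correlation: duplicates, independence, shared gain", {
  set.seed(5)
  x <- rpois(2000, 3)
  r <- spike_raster(rbind(x, x), 15)
  expect_equal(as.numeric(mean_pairwise_correlation(r)), 1)
  r_ind <- poisson_raster(20, 4, 120, seed = 6)
  m <- mean_pairwise_correlation(r_ind)
  expect_lt(abs(m), 3 / sqrt(190 * 8000 / 190))  # ~3 SE of a pair corr
  # doubly-stochastic shared gain induces positive correlations
  set.seed(7)
  gain <- exp(rnorm(3000, 0, 0.8))
  rates <- outer(rep(20, 15), gain)
  r_sh <- spike_raster(matrix(rpois(length(rates), rates * 0.015),
                              nrow = 15), 15)
  expect_gt(as.numeric(mean_pairwise_correlation(r_sh)), 0.2)
  # zero-variance neurons are excluded and counted
  counts <- rbind(matrix(rpois(2000, 2), 2), 0L)
  v <- mean_pairwise_correlation(spike_raster(counts, 15))
  expect_identical(attr(v, "n_excluded"), 1L)
  expect_error(mean_pairwise_correlation(spike_raster(matrix(0L, 3, 10), 15)),
               "degenerate")
})

test_that("statistics are invariant to neuron relabeling", {
  r <- poisson_raster(12, 5, 30, seed = 9)
  perm <- sample(12)
  r2 <- spike_raster(r$counts[perm, ], 15)
  expect_equal(as.numeric(mean_pairwise_correlation(r)),
               as.numeric(mean_pairwise_correlation(r2)))
  expect_equal(compute_mua(r), compute_mua(r2))
  s1 <- summary_stats(r, fit_envelope = FALSE)
  s2 <- summary_stats(r2, fit_envelope = FALSE)
  expect_equal(s1$sorted_mua, s2$sorted_mua)
  expect_equal(s1$pct_silence, s2$pct_silence)
})

test_that("noise correlations: independence null, shared gain, method accord", {
  set.seed(11)
  n_tr <- 40; n_nr <- 12; n_bin <- 30
  psth <- matrix(runif(n_nr * n_bin, 0, 4), n_nr, n_bin)
  mk <- function(extra = 0) {
    a <- array(0, c(n_tr, n_nr, n_bin))
    for (t in 1:n_tr) {
      lam <- psth * 0.5 + extra * rexp(1)
      a[t, , ] <- rpois(n_nr * n_bin, lam)
    }
    a
  }
  ind <- mk(0)
  nc <- noise_correlations(ind, method = "residual")
  expect_lt(abs(nc$mean_noise_corr), 3 / sqrt(n_tr * n_bin))
  expect_true(isSymmetric(nc$c_ij))
  expect_true(all(abs(nc$c_ij) <= 1 + 1e-12, na.rm = TRUE))
  # trial-wise shared additive offset -> positive noise correlations
  sh <- mk(2)
  nc_sh <- noise_correlations(sh, method = "residual")
  expect_gt(nc_sh$mean_noise_corr, 0.05)
  # the shuffle estimator agrees with the residual estimator
  nc_shuf <- noise_correlations(sh, method = "shuffle", n_shuffles = 30)
  expect_lt(abs(nc_shuf$mean_noise_corr - nc_sh$mean_noise_corr), 0.05)
  expect_error(noise_correlations(ind[1, , , drop = FALSE]), "invalid")
})

test_that("neuron subsampling is seed-stable and unbiased", {
  r <- poisson_raster(60, 4, 30, seed = 13)
  expect_identical(subsample_neurons(r, 60), r)
  a <- subsample_neurons(r, 20, seed = 5)
  b <- subsample_neurons(r, 20, seed = 5)
  expect_identical(a$counts, b$counts)
  expect_error(subsample_neurons(r, 61), "invalid")
  # subsample estimate of the mean correlation is consistent with the
  # full-population estimate
  set.seed(14)
  gain <- exp(rnorm(2000, 0, 0.5))
  rates <- outer(rep(4, 120), gain)
  rr <- spike_raster(matrix(rpois(length(rates), rates * 0.015), 120), 15)
  full <- as.numeric(mean_pairwise_correlation(rr))
  subs <- vapply(1:20, function(sd)
    as.numeric(mean_pairwise_correlation(subsample_neurons(rr, 50, sd))),
    numeric(1))
  expect_lt(abs(mean(subs) - full), 3 * sd(subs) / sqrt(20) + 0.01)
})
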