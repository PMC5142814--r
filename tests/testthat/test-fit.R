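# minimal hand-built aqif_stats for cost arithmetic
mk_stats <- function(corr, sorted, acf) {
  structure(list(mean_rate = sum(sorted), mean_pairwise_corr = corr,
                 sorted_mua = sorted, pct_silence = 0,
                 acf = structure(list(lags_ms = seq_along(acf) * 15 - 15,
                                      acf = acf,
                                      fit = c(a = NA, T_decay = NA,
                                              t_period = NA)),
                                 class = "acf_result")),
            class = "aqif_stats")
}

test_that("normalized cost terms follow their defining arithmetic", {
  norm <- list(var_c = 8e-4)
  expect_equal(cost_c(0.1, 0.1, norm), 0)
  expect_equal(cost_c(0.1, 0.1 + sqrt(8e-4), norm), 1)
  expect_equal(cost_c(0.10, 0.06, norm), 2.0)

  d <- c(1, 2, 4); cm <- c(2, 2, 2)
  expect_equal(cost_m(d, d, cm), 0)
  expect_equal(cost_m(d, cm, cm), 1)
  expect_equal(cost_m(d, (d + cm) / 2, cm), 0.25)
  expect_error(cost_m(cm, d, cm), "degenerate")
  expect_equal(cost_a(d, d, cm), 0)
  expect_equal(cost_a(d, cm, cm), 1)
  expect_equal(cost_a(d, (d + cm) / 2, cm), 0.25)
})

test_that("total cost is the exact sum of its three terms", {
  set.seed(1)
  cohort <- lapply(1:6, function(i)
    mk_stats(runif(1, 0, 0.2), runif(5, 0, 4), c(1, runif(4, -0.2, 0.8))))
  data <- cohort[[1]]
  norm <- make_normalizers(data, cohort)
  model <- cohort[[2]]
  cb <- total_cost(data, model, norm)
  expect_equal(cb$total, cb$cost_c + cb$cost_m + cb$cost_a)
  expect_equal(total_cost(data, data, norm)$total, 0)
  # doubling one statistic's deviation from the data quadruples only that
  # term
  model2 <- model
  model2$mean_pairwise_corr <- data$mean_pairwise_corr +
    2 * (model$mean_pairwise_corr - data$mean_pairwise_corr)
  cb2 <- total_cost(data, model2, norm)
  expect_equal(cb2$cost_m, cb$cost_m)
  expect_equal(cb2$cost_a, cb$cost_a)
  expect_equal(cb2$cost_c, 4 * cb$cost_c)
})

test_that("cost smoothing averages each point with its k nearest neighbors", {
  grid <- parameter_grid(default_grid_axes(3))
  n <- nrow(grid$points)
  const <- rep(2.5, n)
  expect_equal(smooth_costs(grid, const, k = 10), const)
  spike <- rep(0, n); spike[50] <- 11
  sm <- smooth_costs(grid, spike, k = 10)
  expect_equal(sm[50], 1)   # reduced by 1/(k+1)
  expect_gte(min(sm), min(spike))
  tiny <- parameter_grid(list(wI = c(0.1, 0.2, 0.3), wA = 0.8, wE = 3,
                              b1 = 0.02, b0 = 0.01))
  expect_error(smooth_costs(tiny, rep(1, 3), k = 10), "invalid")
})

test_that("grid_fit returns the cached point for a one-point grid", {
  grid <- parameter_grid(list(wI = 0.2, wA = 0.8, wE = 3, b1 = 0.02,
                              b0 = 0.01))
  set.seed(2)
  cohort <- lapply(1:4, function(i)
    mk_stats(runif(1, 0, 0.2), runif(5, 0, 4), c(1, runif(4, 0, 0.5))))
  grid$stats[[1]] <- cohort[[2]]
  norm <- make_normalizers(cohort[[1]], cohort)
  fit <- grid_fit(cohort[[1]], grid, norm)
  expect_equal(fit$best_params$wI, 0.2)
  expect_equal(fit$n_evaluations, 1L)
  expect_error(grid_fit(cohort[[1]], parameter_grid(), norm), "empty")
})

test_that("Barker acceptance arithmetic", {
  expect_equal(mcmc_acceptance(1.3, 1.3, 0.5), 0.5)
  expect_equal(mcmc_acceptance(1 + 0.3 * log(3), 1, 0.3), 0.25)
  # T -> 0 greedy; T -> Inf fair coin
  expect_equal(mcmc_acceptance(2, 1, 1e-9), 0)
  expect_equal(mcmc_acceptance(1, 2, 1e-9), 1)
  expect_equal(mcmc_acceptance(5, 1, 1e9), 0.5, tolerance = 1e-6)
})

test_that("MCMC finds the minimum of a toy grid with few evaluations", {
  # deterministic toy cost: quadratic bowl over the grid indices with the
  # optimum planted off-center; the evaluator returns stats whose cost
  # against the data reproduces that bowl
  grid <- parameter_grid(default_grid_axes(5))
  target_idx <- c(4, 2, 3, 5, 2)
  set.seed(3)
  cohort <- lapply(1:6, function(i)
    mk_stats(runif(1, 0.05, 0.2), runif(5, 1, 4), c(1, runif(4, 0, 0.5))))
  data <- cohort[[1]]
  norm <- make_normalizers(data, cohort)
  # evaluator: corr displaced from the data value by the index distance
  mk_eval <- function() {
    function(params) {
      idx <- vapply(free_param_names(), function(nm)
        which.min(abs(grid$axes[[nm]] - params[[nm]])), integer(1))
      d2 <- sum((idx - target_idx)^2)
      s <- data
      s$mean_pairwise_corr <- data$mean_pairwise_corr +
        sqrt(norm$var_c * d2) * 0.5
      s
    }
  }
  found <- 0L; evals <- integer(10)
  for (sd in 1:10) {
    fit <- mcmc_fit(data, grid, norm, sampler_config(max_samples = 300),
                    evaluator = mk_eval(), seed = sd)
    if (all(grid$idx[fit$best_index, ] == target_idx)) found <- found + 1L
    evals[sd] <- fit$n_evaluations
  }
  expect_gte(found, 9L)
  # well under 10% of the 3125-point grid actually simulated
  expect_true(all(evals <= 312))
})

test_that("split-half variance explained approaches 1 for stationary data", {
  r_long <- poisson_raster(30, 6, 240, seed = 4)
  ve <- split_half_variance(r_long)$ve
  expect_gt(ve[["sorted_mua"]], 0.9)
  # halves of white-noise-like ACF explain ~none of each other's variance
  expect_lt(abs(ve[["acf"]]) , 1)   # finite, possibly near 0 or negative
  expect_error(split_half_variance(poisson_raster(5, 5, 10, seed = 1)),
               "invalid")
  # cohort version pools scalar statistics
  cohort <- lapply(1:6, function(i) poisson_raster(20, i + 1, 120, seed = i))
  vc <- split_half_variance_cohort(cohort)
  expect_gt(vc$ve[["mean_rate"]], 0.95)
})

test_that("transition refits nest: pairs beat singles beat no change", {
  set.seed(5)
  cohort <- lapply(1:6, function(i)
    mk_stats(runif(1, 0.05, 0.25), sort(runif(6, 0, 4)),
             c(1, runif(5, 0, 0.6))))
  running <- cohort[[1]]
  norm <- make_normalizers(running, cohort)
  base <- model_params(wI = 0.2, wA = 0.9, wE = 3.5, b1 = 0.05, b0 = 0.02)
  # synthetic evaluator: cost minimized at a planted (wI, wA) combination
  planted <- c(wI = 0.35, wA = 0.55)
  eval_fn <- function(params) {
    d2 <- (params$wI - planted[["wI"]])^2 / 0.4^2 +
      (params$wA - planted[["wA"]])^2 / 1^2 +
      (params$wE - base$wE)^2 + (params$b1 - base$b1)^2 +
      (params$b0 - base$b0)^2
    s <- running
    s$mean_pairwise_corr <- running$mean_pairwise_corr +
      sqrt(norm$var_c) * 5 * sqrt(d2)
    s
  }
  refit <- refit_transition(base, running, norm, eval_fn,
                            axes = default_grid_axes(5))
  best_pair <- min(refit$cost_matrix[upper.tri(refit$cost_matrix)])
  best_single <- min(diag(refit$cost_matrix))
  expect_lte(best_pair, best_single)
  expect_lte(best_single, refit$zero_change_cost)
  expect_identical(refit$best_pair, "wI+wA")
  # no-change data: zero-change already optimal
  refit0 <- refit_transition(base, running, norm, function(params) {
    s <- running
    d2 <- sum((unlist(params[free_param_names()]) -
                 unlist(base[free_param_names()]))^2)
    s$mean_pairwise_corr <- running$mean_pairwise_corr +
      sqrt(norm$var_c) * 5 * sqrt(d2)
    s
  }, axes = default_grid_axes(5))
  expect_equal(min(refit0$table$best_cost), refit0$zero_change_cost,
               tolerance = 1e-10)
})

test_that("fitted inhibition predicts evoked decorrelation across a cohort", {
  # cohort of synthetic model recordings differing only in their true wI;
  # wI is refit on its axis and the evoked noise correlation of each
  # fitted model is measured: the relation must be strongly negative
  true_wi <- c(0.05, 0.12, 0.19, 0.26, 0.33, 0.40)
  wi_axis <- seq(0.01, 0.4, length.out = 8)
  ev <- grid_evaluator(duration_s = 45, seed = 11, max_lag_ms = 900)
  data_stats <- lapply(seq_along(true_wi), function(i) {
    p <- model_params(wI = true_wi[i])
    J <- build_connectivity(p$N, p$p_conn, p$wE, seed = 11)
    b <- draw_tonic_input(p$N, p$b0, p$b1, seed = 12)
    sim <- simulate_network(p, J = J, b = b, duration_s = 120,
                            seed = 500 + i, burn_in_s = 5)
    summary_stats(subsample_neurons(bin_raster(sim, 15), 50, seed = 11),
                  fit_envelope = FALSE, max_lag_ms = 900)
  })
  ic <- gen_ic_psths(mode = "speech", duration_s = 1.2, seed = 5)
  fitted_wi <- numeric(length(true_wi))
  evoked_corr <- numeric(length(true_wi))
  for (i in seq_along(true_wi)) {
    norm <- make_normalizers(data_stats[[i]], data_stats)
    costs <- vapply(wi_axis, function(wi)
      total_cost(data_stats[[i]], ev(model_params(wI = wi)), norm)$total,
      numeric(1))
    fitted_wi[i] <- wi_axis[which.min(costs)]
    pf <- model_params(wI = fitted_wi[i])
    inp <- build_external_input(ic, pf$N, seed = 3)
    evk <- simulate_evoked(pf, inp, n_trials = 25, seed = 1)
    set.seed(9)
    sel <- sample(pf$N, 50)
    evoked_corr[i] <- evoked_noise_correlations(evk,
                                                neurons = sel)$mean_noise_corr
  }
  expect_lt(cor(fitted_wi, evoked_corr, method = "spearman"), -0.8)
})
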