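#' Normalizers for the three cost terms
#'
#' The three cost terms are normalized to order 1 so they can be summed.
#' The correlation term is divided by the variance of the mean pairwise
#' correlation across the recording collection; the MUA-distribution and
#' ACF terms are divided by the squared distance between the target
#' recording's statistic and the collection mean of that statistic, so each
#' measures how much closer the simulation is to the recording than the
#' average of all recordings is.
#'
#' @param data_stats the [summary_stats()] of the recording being fit.
#' @param cohort_stats list of [summary_stats()] for the full recording
#'   collection (the target may be among them); at least 2.
#' @return List of class `aqif_normalizers` with `var_c`, `dm_norm`,
#'   `da_norm` and the collection means `mean_sorted`, `mean_acf`.
#' @export
make_normalizers <- function(data_stats, cohort_stats) {
  stopifnot(inherits(data_stats, "aqif_stats"), length(cohort_stats) >= 2)
  cs <- vapply(cohort_stats, function(s) s$mean_pairwise_corr, numeric(1))
  var_c <- mean((cs - mean(cs))^2)
  sorted_mat <- vapply(cohort_stats, function(s) s$sorted_mua,
                       numeric(length(data_stats$sorted_mua)))
  mean_sorted <- rowMeans(sorted_mat)
  acf_mat <- vapply(cohort_stats, function(s) s$acf$acf,
                    numeric(length(data_stats$acf$acf)))
  mean_acf <- rowMeans(acf_mat)
  dm_norm <- sum((data_stats$sorted_mua - mean_sorted)^2)
  da_norm <- sum((data_stats$acf$acf - mean_acf)^2)
  if (var_c <= 0 || dm_norm <= 0 || da_norm <= 0)
    stop("degenerate collection: a cost normalizer is zero")
  structure(list(var_c = var_c, dm_norm = dm_norm, da_norm = da_norm,
                 mean_sorted = mean_sorted, mean_acf = mean_acf),
            class = "aqif_normalizers")
}

#' Normalized cost terms
#'
#' `cost_c` is the squared difference of mean pairwise correlations divided
#' by the across-collection variance of that statistic. `cost_m` and
#' `cost_a` are squared differences summed over rank bins (sorted MUA
#' distribution) or lag bins (MUA ACF), divided by the squared distance
#' between the recording and the collection mean, so a value of 1 means the
#' model does no better than the average recording.
#'
#' @param c_data,c_model mean pairwise correlations of recording and model.
#' @param norm an [make_normalizers()] object.
#' @return Scalar non-negative cost.
#' @export
cost_c <- function(c_data, c_model, norm) {
  if (norm$var_c <= 0) stop("degenerate collection: zero correlation variance")
  (c_data - c_model)^2 / norm$var_c
}

#' @rdname cost_c
#' @param sorted_mua_data,sorted_mua_model,sorted_mua_collection_mean
#'   sorted MUA distributions on a common rank-bin grid.
#' @export
cost_m <- function(sorted_mua_data, sorted_mua_model,
                   sorted_mua_collection_mean) {
  denom <- sum((sorted_mua_data - sorted_mua_collection_mean)^2)
  if (denom <= 0)
    stop("degenerate collection: recording equals the collection mean")
  sum((sorted_mua_data - sorted_mua_model)^2) / denom
}

#' @rdname cost_c
#' @param acf_data,acf_model,acf_collection_mean MUA autocorrelation
#'   functions on a common lag grid.
#' @export
cost_a <- function(acf_data, acf_model, acf_collection_mean) {
  denom <- sum((acf_data - acf_collection_mean)^2)
  if (denom <= 0)
    stop("degenerate collection: recording equals the collection mean")
  sum((acf_data - acf_model)^2) / denom
}

#' Total normalized cost of a model against a recording
#'
#' @param stats_data,stats_model [summary_stats()] of recording and model
#'   on identical rank/lag grids.
#' @param norm an [make_normalizers()] object built for `stats_data`.
#' @return List of class `cost_breakdown` with `cost_c`, `cost_m`,
#'   `cost_a` and `total` (their sum).
#' @export
total_cost <- function(stats_data, stats_model, norm) {
  cc <- cost_c(stats_data$mean_pairwise_corr,
               stats_model$mean_pairwise_corr, norm)
  cm <- sum((stats_data$sorted_mua - stats_model$sorted_mua)^2) / norm$dm_norm
  ca <- sum((stats_data$acf$acf - stats_model$acf$acf)^2) / norm$da_norm
  structure(list(cost_c = cc, cost_m = cm, cost_a = ca,
                 total = cc + cm + ca), class = "cost_breakdown")
}

#' Parameter grid for fitting
#'
#' A full factorial grid over the five free parameters, with a cache of
#' summary statistics per grid point. The default axes place
#' `n_per_axis` equally spaced values across each fitting range.
#'
#' @param axes named list (`wI`, `wA`, `wE`, `b1`, `b0`) of sorted axis
#'   values; defaults to [default_grid_axes()].
#' @return Object of class `parameter_grid`: list with `axes`, `points`
#'   (data frame of coordinates), `idx` (matrix of axis indices) and
#'   `stats` (list, `NULL` until populated).
#' @export
parameter_grid <- function(axes = default_grid_axes()) {
  stopifnot(setequal(names(axes), free_param_names()))
  axes <- axes[free_param_names()]
  r <- param_ranges()
  idx <- as.matrix(expand.grid(lapply(axes, seq_along),
                               KEEP.OUT.ATTRS = FALSE))
  points <- as.data.frame(mapply(function(a, i) a[i], axes,
                                 as.data.frame(idx), SIMPLIFY = FALSE))
  structure(list(axes = axes, points = points, idx = idx,
                 stats = vector("list", nrow(points))),
            class = "parameter_grid")
}

#' @rdname parameter_grid
#' @param n_per_axis number of grid values per parameter axis.
#' @export
default_grid_axes <- function(n_per_axis = 4L) {
  lapply(param_ranges(), function(r) seq(r[1], r[2], length.out = n_per_axis))
}

#' Simulation-based evaluator of summary statistics at a parameter point
#'
#' Returns a function `params -> aqif_stats` that simulates the network and
#' computes the fitted statistics on a 50-neuron subsample, with a
#' memoising cache keyed by the parameter coordinates so repeated
#' evaluations (e.g. across refit sub-grids) are free.
#'
#' @param duration_s simulated duration per evaluation.
#' @param seed seed shared by every evaluation (connectivity, tonic input,
#'   initial state, subsample).
#' @param subsample neurons used for statistics (`NULL` = all).
#' @param max_lag_ms,n_rank_bins statistic grids (must match the data's).
#' @param burn_in_s discarded transient.
#' @param n_reps network realizations averaged per evaluation. The
#'   connectivity, tonic input and 50-neuron subsample are random
#'   ingredients of the model, and a single realization's statistics carry
#'   substantial realization noise; averaging the statistics of a few
#'   independent realizations gives a less noisy estimate of the expected
#'   statistics at a parameter point.
#' @return A memoised evaluator function.
#' @export
grid_evaluator <- function(duration_s = 60, seed = 1L, subsample = 50L,
                           max_lag_ms = 600, n_rank_bins = 100L,
                           burn_in_s = 5, n_reps = 1L) {
  cache <- new.env(parent = emptyenv())
  function(params) {
    key <- paste(signif(unlist(params[free_param_names()]), 12),
                 collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    reps <- lapply(seq_len(n_reps), function(rep) {
      sd <- seed + 7919L * (rep - 1L)
      sim <- simulate_network(params, duration_s = duration_s, seed = sd,
                              burn_in_s = burn_in_s)
      r <- bin_raster(sim, 15)
      if (!is.null(subsample) && subsample < r$n_neurons)
        r <- subsample_neurons(r, subsample, seed = sd)
      summary_stats(r, max_lag_ms = max_lag_ms, n_rank_bins = n_rank_bins,
                    fit_envelope = FALSE)
    })
    s <- average_stats(reps)
    cache[[key]] <- s
    s
  }
}

# elementwise average of aqif_stats over realizations; NA scalars (silent
# realizations) are dropped from the scalar means
average_stats <- function(stat_list) {
  if (length(stat_list) == 1) return(stat_list[[1]])
  out <- stat_list[[1]]
  out$mean_rate <- mean(vapply(stat_list, `[[`, numeric(1), "mean_rate"))
  mc <- vapply(stat_list, `[[`, numeric(1), "mean_pairwise_corr")
  out$mean_pairwise_corr <- if (all(is.na(mc))) NA_real_
    else mean(mc, na.rm = TRUE)
  out$pct_silence <- mean(vapply(stat_list, `[[`, numeric(1), "pct_silence"))
  out$sorted_mua <- rowMeans(vapply(stat_list, `[[`,
                                    numeric(length(out$sorted_mua)),
                                    "sorted_mua"))
  out$acf$acf <- rowMeans(vapply(stat_list, function(s) s$acf$acf,
                                 numeric(length(out$acf$acf))))
  out
}

#' Populate the statistics cache of a grid
#'
#' @param grid a [parameter_grid()].
#' @param evaluator a `params -> aqif_stats` function, e.g.
#'   [grid_evaluator()].
#' @param base an [model_params()] object supplying the fixed constants.
#' @param progress print a dot every 100 points.
#' @param which indices of the grid points to evaluate (default all);
#'   points left unevaluated are simply absent from the cache, so a sparse
#'   random design over a fine grid can be fit without simulating the full
#'   factorial.
#' @return The grid with `stats` filled in.
#' @export
populate_grid <- function(grid, evaluator, base = model_params(),
                          progress = FALSE, which = seq_len(nrow(grid$points))) {
  for (g in which) {
    if (is.null(grid$stats[[g]])) {
      p <- base
      p[free_param_names()] <- as.list(grid$points[g, ])
      grid$stats[[g]] <- evaluator(p)
    }
    if (progress && g %% 100 == 0) cat(".")
  }
  if (progress) cat("\n")
  grid
}

#' Neighborhood smoothing of grid costs
#'
#' Each point's cost is replaced by the mean of itself and its `k` nearest
#' grid neighbors, nearness measured in axis-index space (one grid step =
#' one unit on every axis, so incommensurable parameter units do not mix).
#' Smoothing removes part of the simulation sampling noise before the
#' minimizer is taken.
#'
#' @param grid a [parameter_grid()].
#' @param costs numeric vector of raw costs, one per grid point.
#' @param k number of neighbors averaged with each point.
#' @return Numeric vector of smoothed costs.
#' @export
smooth_costs <- function(grid, costs, k = 10L) {
  n <- nrow(grid$idx)
  if (n < k + 1) stop("invalid argument: need at least k + 1 grid points")
  d <- as.matrix(stats::dist(grid$idx))
  vapply(seq_len(n), function(g) {
    nb <- order(d[g, ])[seq_len(k + 1)]   # includes the point itself
    mean(costs[nb])
  }, numeric(1))
}

#' Grid-search fit
#'
#' Evaluates the normalized cost of every cached grid point against the
#' recording, smooths the cost field over the `k` nearest neighbors, and
#' returns the minimizer of the smoothed cost. Ties are broken by lowest
#' raw cost, then by lexicographic parameter order.
#'
#' @param data_stats [summary_stats()] of the recording.
#' @param grid a populated [parameter_grid()].
#' @param norm an [make_normalizers()] object for this recording.
#' @param k_smooth neighbors used by [smooth_costs()].
#' @param base [model_params()] supplying fixed constants for the result.
#' @return Object of class `aqif_fit`: list with `best_params`,
#'   `best_cost` (raw [total_cost()] breakdown at the winner), `best_index`,
#'   `costs`, `smoothed`, `n_evaluations`.
#' @export
grid_fit <- function(data_stats, grid, norm, k_smooth = 10L,
                     base = model_params()) {
  filled <- !vapply(grid$stats, is.null, logical(1))
  if (!any(filled)) stop("invalid argument: grid cache is empty")
  sub <- grid
  sub$points <- grid$points[filled, , drop = FALSE]
  sub$idx <- grid$idx[filled, , drop = FALSE]
  sub$stats <- grid$stats[filled]
  costs <- vapply(sub$stats,
                  function(s) total_cost(data_stats, s, norm)$total,
                  numeric(1))
  # degenerate model stats (silent networks) must never win, but an Inf
  # would poison every smoothing neighborhood it touches, so cap at the
  # worst finite cost instead
  if (any(!is.finite(costs))) {
    cap <- if (any(is.finite(costs))) max(costs[is.finite(costs)]) else 1e6
    costs[!is.finite(costs)] <- cap
  }
  smoothed <- if (nrow(sub$points) > k_smooth)
    smooth_costs(sub, costs, k_smooth) else costs
  ord <- do.call(order, c(list(smoothed, costs), as.list(sub$points)))
  best <- ord[1]
  bp <- base
  bp[free_param_names()] <- as.list(sub$points[best, ])
  structure(list(best_params = bp,
                 best_cost = total_cost(data_stats, sub$stats[[best]], norm),
                 best_smoothed = smoothed[best],
                 best_index = which(filled)[best],
                 costs = costs, smoothed = smoothed,
                 n_evaluations = length(costs)),
            class = "aqif_fit")
}

#' @export
print.aqif_fit <- function(x, ...) {
  p <- x$best_params
  cat(sprintf(paste0("aqif_fit: wI=%.3g wA=%.3g wE=%.3g b1=%.3g b0=%.3g ",
                     "(cost %.3g = c %.3g + m %.3g + a %.3g; %d evals)\n"),
              p$wI, p$wA, p$wE, p$b1, p$b0, x$best_cost$total,
              x$best_cost$cost_c, x$best_cost$cost_m, x$best_cost$cost_a,
              x$n_evaluations))
  invisible(x)
}

#' Sampler configuration for the MCMC fit
#'
#' @param temperature MCMC temperature `T` in `P = exp(-Cost / T)`.
#' @param restart_interval chain restart period (samples).
#' @param max_samples total samples drawn.
#' @param anneal if `TRUE`, multiply the temperature by `anneal_factor`
#'   after every restart (simulated annealing).
#' @param anneal_factor geometric cooling factor.
#' @return List of class `sampler_config`.
#' @export
sampler_config <- function(temperature = 0.3, restart_interval = 50L,
                           max_samples = 500L, anneal = FALSE,
                           anneal_factor = 0.9) {
  stopifnot(temperature > 0, restart_interval >= 2, max_samples >= 1)
  structure(list(temperature = temperature,
                 restart_interval = as.integer(restart_interval),
                 max_samples = as.integer(max_samples),
                 anneal = anneal, anneal_factor = anneal_factor),
            class = "sampler_config")
}

#' Barker acceptance probability
#'
#' `P(accept) = P(new) / (P(new) + P(old)) = 1 / (1 + exp((Cost_new -
#' Cost_old) / T))`. Equal costs give 1/2; as `T -> 0` the rule becomes
#' greedy descent, as `T -> Inf` it becomes a fair coin.
#'
#' @param cost_new,cost_old total costs of proposal and current point.
#' @param temperature MCMC temperature.
#' @return Acceptance probability in `[0, 1]`.
#' @export
mcmc_acceptance <- function(cost_new, cost_old, temperature) {
  1 / (1 + exp((cost_new - cost_old) / temperature))
}

#' MCMC (Gibbs-sampling-style) fit over the parameter grid
#'
#' Samples the grid with neighbor proposals (one axis moved one step) and
#' the Barker acceptance rule on `P = exp(-Cost / T)`. Every
#' `restart_interval` samples the chain restarts from the pool of
#' already-sampled points, chosen with probability proportional to
#' `P(theta)`; the pool may be shared across recordings to reuse
#' simulations. Grid points are evaluated lazily through the evaluator, so
#' far fewer simulations are needed than a full grid sweep.
#'
#' @param data_stats [summary_stats()] of the recording.
#' @param grid a [parameter_grid()] (its cache is used and extended).
#' @param norm [make_normalizers()] for this recording.
#' @param sampler a [sampler_config()].
#' @param evaluator `params -> aqif_stats` function (see
#'   [grid_evaluator()]); a failed evaluation is assigned infinite cost.
#' @param base [model_params()] supplying fixed constants.
#' @param seed seed for proposals and restarts.
#' @param pool optional environment carrying `idx`/`cost` vectors pooled
#'   across recordings; updated in place.
#' @return An `aqif_fit` with a `trace` data frame (`sample`, `index`,
#'   `cost`, `accepted`) and `n_evaluations` the number of distinct
#'   simulations run.
#' @export
mcmc_fit <- function(data_stats, grid, norm, sampler = sampler_config(),
                     evaluator, base = model_params(), seed = 1L,
                     pool = NULL) {
  set.seed(seed)
  n_axis <- vapply(grid$axes, length, integer(1))
  key_of <- function(iv) paste(iv, collapse = ",")
  idx_lookup <- new.env(parent = emptyenv())
  for (g in seq_len(nrow(grid$idx))) idx_lookup[[key_of(grid$idx[g, ])]] <- g
  cost_cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  eval_point <- function(g) {
    key <- as.character(g)
    if (!is.null(cost_cache[[key]])) return(cost_cache[[key]])
    if (is.null(grid$stats[[g]])) {
      p <- base
      p[free_param_names()] <- as.list(grid$points[g, ])
      grid$stats[[g]] <<- tryCatch(evaluator(p), error = function(e) NA)
      n_eval <<- n_eval + 1L
    }
    s <- grid$stats[[g]]
    cst <- if (inherits(s, "aqif_stats"))
      total_cost(data_stats, s, norm)$total else Inf
    if (!is.finite(cst)) cst <- Inf
    cost_cache[[key]] <- cst
    cst
  }
  if (is.null(pool)) {
    pool <- new.env(parent = emptyenv())
  }
  if (is.null(pool$idx)) { pool$idx <- integer(0); pool$cost <- numeric(0) }

  temp <- sampler$temperature
  cur <- sample.int(nrow(grid$idx), 1)
  cur_cost <- eval_point(cur)
  trace <- data.frame(sample = seq_len(sampler$max_samples),
                      index = NA_integer_, cost = NA_real_, accepted = NA)
  best <- cur; best_cost <- cur_cost
  for (s in seq_len(sampler$max_samples)) {
    if (s %% sampler$restart_interval == 0 && length(pool$idx) > 0) {
      w <- exp(-(pool$cost - min(pool$cost)) / temp)
      cur <- pool$idx[sample.int(length(pool$idx), 1, prob = w)]
      cur_cost <- eval_point(cur)
      if (sampler$anneal) temp <- temp * sampler$anneal_factor
    }
    iv <- grid$idx[cur, ]
    ax <- sample.int(length(n_axis), 1)
    step <- sample(c(-1L, 1L), 1)
    iv2 <- iv
    iv2[ax] <- min(n_axis[ax], max(1L, iv[ax] + step))
    prop <- idx_lookup[[key_of(iv2)]]
    prop_cost <- eval_point(prop)
    acc <- stats::runif(1) < mcmc_acceptance(prop_cost, cur_cost, temp)
    if (acc) { cur <- prop; cur_cost <- prop_cost }
    if (is.finite(prop_cost)) {
      pool$idx <- c(pool$idx, prop); pool$cost <- c(pool$cost, prop_cost)
    }
    if (cur_cost < best_cost) { best <- cur; best_cost <- cur_cost }
    trace$index[s] <- cur; trace$cost[s] <- cur_cost; trace$accepted[s] <- acc
  }
  bp <- base
  bp[free_param_names()] <- as.list(grid$points[best, ])
  structure(list(best_params = bp,
                 best_cost = total_cost(data_stats, grid$stats[[best]], norm),
                 best_index = best, trace = trace,
                 n_evaluations = n_eval, temperature_final = temp),
            class = "aqif_fit")
}

#' Split-half variance explained
#'
#' Splits a recording into two halves made of interleaved segments
#' (default 4 s), computes each statistic on both halves, and reports for
#' each vector statistic the fraction of variance in one half explained by
#' the other: `1 - sum((h1 - h2)^2) / sum((h1 - mean(h1))^2)`. This is the
#' noise ceiling against which model fits are judged. Scalar statistics
#' have no within-recording variance, so their split-half agreement is
#' pooled across a cohort by [split_half_variance_cohort()].
#'
#' @param raster a [spike_raster()] of at least 16 s.
#' @param seg_s segment length (s).
#' @param ... passed to [summary_stats()].
#' @return List with `ve` (named vector: `acf`, `sorted_mua`), and the two
#'   halves' `aqif_stats`. Negative fractions are reported as computed,
#'   with a `flag` attribute.
#' @export
split_half_variance <- function(raster, seg_s = 4, ...) {
  stopifnot(inherits(raster, "spike_raster"))
  if (raster$duration_s < 4 * seg_s)
    stop("invalid argument: recording shorter than four segments")
  bins_per_seg <- as.integer(round(seg_s * 1000 / raster$bin_ms))
  seg <- (seq_len(ncol(raster$counts)) - 1L) %/% bins_per_seg
  h1 <- raster$counts[, seg %% 2L == 0L, drop = FALSE]
  h2 <- raster$counts[, seg %% 2L == 1L, drop = FALSE]
  s1 <- summary_stats(spike_raster(h1, raster$bin_ms), fit_envelope = FALSE,
                      ...)
  s2 <- summary_stats(spike_raster(h2, raster$bin_ms), fit_envelope = FALSE,
                      ...)
  ve_of <- function(a, b) 1 - sum((a - b)^2) / sum((a - mean(a))^2)
  ve <- c(acf = ve_of(s1$acf$acf[-1], s2$acf$acf[-1]),
          sorted_mua = ve_of(s1$sorted_mua, s2$sorted_mua))
  out <- list(ve = ve, half1 = s1, half2 = s2)
  if (any(ve < 0)) attr(out$ve, "flag") <- "negative variance explained"
  out
}

#' @rdname split_half_variance
#' @param rasters list of [spike_raster()] recordings.
#' @return For the cohort version, a list with `ve` including the pooled
#'   scalar statistics (`mean_corr`, `mean_rate`) and the per-recording
#'   vector fractions.
#' @export
split_half_variance_cohort <- function(rasters, seg_s = 4, ...) {
  per <- lapply(rasters, split_half_variance, seg_s = seg_s, ...)
  ve_of <- function(a, b) 1 - sum((a - b)^2) / sum((a - mean(a))^2)
  c1 <- vapply(per, function(x) x$half1$mean_pairwise_corr, numeric(1))
  c2 <- vapply(per, function(x) x$half2$mean_pairwise_corr, numeric(1))
  r1 <- vapply(per, function(x) x$half1$mean_rate, numeric(1))
  r2 <- vapply(per, function(x) x$half2$mean_rate, numeric(1))
  list(ve = c(mean_corr = ve_of(c1, c2), mean_rate = ve_of(r1, r2),
              acf = mean(vapply(per, function(x) x$ve[["acf"]], numeric(1))),
              sorted_mua = mean(vapply(per, function(x) x$ve[["sorted_mua"]],
                                       numeric(1)))),
       per_recording = per)
}

#' Refit the stationary model to running-period statistics
#'
#' Starting from a stationary-period fit, re-optimizes each single
#' parameter and each parameter pair over its sub-grid with all other
#' parameters frozen, and tabulates the best cost of every refit option.
#' The stationary value is included on every refit axis, so the no-change
#' model is nested in every option and the pair costs are never above the
#' single costs.
#'
#' @param stationary_fit an `aqif_fit` (or an [model_params()] object) for
#'   the stationary periods.
#' @param running_stats [summary_stats()] of the running periods.
#' @param norm [make_normalizers()] for the running statistics.
#' @param evaluator `params -> aqif_stats` function; use a memoising
#'   [grid_evaluator()] so shared sub-grid points are simulated once.
#' @param axes refit axes per parameter (defaults to
#'   [default_grid_axes()]).
#' @return List of class `aqif_refit` with `cost_matrix` (5 x 5: diagonal =
#'   single-parameter best costs, off-diagonal = pair best costs),
#'   `zero_change_cost`, `best_single`, `best_pair`, and `table` (ranked
#'   data frame of all 15 options with their refit values).
#' @export
refit_transition <- function(stationary_fit, running_stats, norm, evaluator,
                             axes = default_grid_axes()) {
  base <- if (inherits(stationary_fit, "aqif_fit"))
    stationary_fit$best_params else stationary_fit
  stopifnot(inherits(base, "aqif_params"))
  nms <- free_param_names()
  axes <- lapply(stats::setNames(nms, nms), function(nm)
    sort(unique(c(axes[[nm]], base[[nm]]))))
  cost_at <- function(vals) {
    p <- base
    p[names(vals)] <- as.list(vals)
    cst <- tryCatch(total_cost(running_stats, evaluator(p), norm)$total,
                    error = function(e) Inf)
    if (is.finite(cst)) cst else Inf
  }
  zero_cost <- cost_at(stats::setNames(numeric(0), character(0)))
  cost_matrix <- matrix(NA_real_, 5, 5, dimnames = list(nms, nms))
  rows <- list()
  for (i in seq_along(nms)) {
    ci <- vapply(axes[[nms[i]]], function(v)
      cost_at(stats::setNames(v, nms[i])), numeric(1))
    cost_matrix[i, i] <- min(ci)
    rows[[length(rows) + 1]] <- data.frame(
      params = nms[i], n_changed = 1L, best_cost = min(ci),
      value1 = axes[[nms[i]]][which.min(ci)], value2 = NA_real_)
  }
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (i >= j) next
    gridij <- expand.grid(v1 = axes[[nms[i]]], v2 = axes[[nms[j]]])
    cij <- vapply(seq_len(nrow(gridij)), function(g)
      cost_at(stats::setNames(c(gridij$v1[g], gridij$v2[g]),
                              c(nms[i], nms[j]))), numeric(1))
    k <- which.min(cij)
    cost_matrix[i, j] <- cost_matrix[j, i] <- cij[k]
    rows[[length(rows) + 1]] <- data.frame(
      params = paste(nms[i], nms[j], sep = "+"), n_changed = 2L,
      best_cost = cij[k], value1 = gridij$v1[k], value2 = gridij$v2[k])
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$best_cost), ]
  rownames(tab) <- NULL
  structure(list(cost_matrix = cost_matrix, zero_change_cost = zero_cost,
                 best_single = tab$params[tab$n_changed == 1][1],
                 best_pair = tab$params[tab$n_changed == 2][1],
                 table = tab),
            class = "aqif_refit")
}
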