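#' Multi-unit activity (MUA)
#'
#' Sum of spikes over all neurons per time bin. If the raster is at a finer
#' resolution than `bin_ms`, counts are re-binned (the raster bin width
#' must divide `bin_ms`).
#'
#' @param raster a [spike_raster()].
#' @param bin_ms output bin width in ms (default 15).
#' @return Numeric vector of per-bin population counts, with attribute
#'   `bin_ms`.
#' @export
compute_mua <- function(raster, bin_ms = 15) {
  stopifnot(inherits(raster, "spike_raster"))
  if (ncol(raster$counts) == 0) stop("empty raster")
  fac <- bin_ms / raster$bin_ms
  if (abs(fac - round(fac)) > 1e-9)
    stop("raster bin width must divide the MUA bin width")
  fac <- as.integer(round(fac))
  mua <- colSums(raster$counts)
  if (fac > 1) {
    n_out <- length(mua) %/% fac
    mua <- colSums(matrix(mua[seq_len(n_out * fac)], nrow = fac))
  }
  structure(as.numeric(mua), bin_ms = bin_ms)
}

#' High-pass filter the MUA at 1 Hz
#'
#' Removes slow (tens of seconds) rate drifts before the autocorrelation is
#' computed, as done for awake recordings. A zero-phase 4th-order
#' Butterworth filter is used.
#'
#' @param mua numeric MUA trace with attribute `bin_ms` (or supply
#'   `bin_ms`).
#' @param cutoff_hz high-pass cutoff (default 1 Hz).
#' @param bin_ms bin width in ms, taken from the trace attribute if absent.
#' @return Filtered trace (signed, near-zero mean), same attributes.
#' @export
highpass_mua <- function(mua, cutoff_hz = 1, bin_ms = attr(mua, "bin_ms")) {
  stopifnot(!is.null(bin_ms))
  if (length(mua) < 30) stop("invalid argument: trace too short to filter")
  fs <- 1000 / bin_ms
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "high")
  # remove the DC component first: the high-pass kills it anyway and the
  # zero-phase filter's edge transients shrink accordingly
  out <- signal::filtfilt(bf, as.numeric(mua) - mean(mua))
  structure(out, bin_ms = bin_ms)
}

#' Autocorrelation function of the MUA
#'
#' Computed on the mean-subtracted trace and normalized so that the zero-lag
#' value is 1; one side is returned.
#'
#' @param mua numeric MUA trace with attribute `bin_ms`.
#' @param max_lag_ms largest lag returned (must be below half the trace
#'   duration).
#' @param bin_ms bin width in ms.
#' @return An object of class `acf_result`: list with `lags_ms`, `acf`, and
#'   a `fit` slot (`NA` until [fit_acf_envelope()] is applied).
#' @export
mua_acf <- function(mua, max_lag_ms = 600, bin_ms = attr(mua, "bin_ms")) {
  stopifnot(!is.null(bin_ms))
  n_lags <- as.integer(floor(max_lag_ms / bin_ms))
  if (n_lags >= length(mua) / 2)
    stop("invalid argument: max_lag must be below half the trace duration")
  if (stats::var(as.numeric(mua)) == 0)
    stop("degenerate input: zero-variance MUA trace")
  a <- stats::acf(as.numeric(mua), lag.max = n_lags, plot = FALSE,
                  demean = TRUE)$acf[, 1, 1]
  structure(list(lags_ms = (0:n_lags) * bin_ms, acf = as.numeric(a),
                 fit = c(a = NA_real_, T_decay = NA_real_,
                         t_period = NA_real_)),
            class = "acf_result")
}

#' Fit the parametric ACF envelope
#'
#' Least-squares fit of `a * exp(-lag / T) * cos(lag / (2 * pi * t_period))`
#' to one side of the ACF. `T` ("autocorr decay") measures the duration
#' over which the MUA stays correlated; the cosine captures an oscillatory
#' component that is not always present, in which case `t_period` runs to
#' its upper bound and the envelope degenerates to a pure exponential.
#'
#' @param acf_res an [mua_acf()] result.
#' @param T_bounds lower/upper bounds on the decay time (ms).
#' @return The input with `fit = c(a, T_decay, t_period)` populated.
#' @export
fit_acf_envelope <- function(acf_res, T_bounds = c(1, 1e4)) {
  stopifnot(inherits(acf_res, "acf_result"))
  lag <- acf_res$lags_ms
  y <- acf_res$acf
  if (length(lag) < 10) stop("invalid argument: need at least 10 lags")
  if (all(abs(y[-1]) < 1e-12)) {
    acf_res$fit <- c(a = y[1], T_decay = T_bounds[1], t_period = 1e6)
    attr(acf_res$fit, "flag") <- "degenerate: no correlation beyond lag 0"
    return(acf_res)
  }
  # crude decay start: first crossing of 1/e
  below <- which(y < exp(-1))
  T0 <- if (length(below)) max(lag[below[1]], bin_of(lag)) else max(lag) / 2
  d <- data.frame(lag = lag, y = y)
  best <- NULL
  for (tp0 in c(1e5, 50, 10)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-lag / Td) * cos(lag / (2 * pi * tp)),
                        data = d,
                        start = list(a = max(y), Td = T0, tp = tp0),
                        lower = c(a = 0, Td = T_bounds[1], tp = 0.5),
                        upper = c(a = 2, Td = T_bounds[2], tp = 1e6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("fit failure: ACF envelope did not converge; residual trace sd = ",
         signif(stats::sd(y), 3))
  cf <- stats::coef(best$fit)
  acf_res$fit <- c(a = unname(cf["a"]), T_decay = unname(cf["Td"]),
                   t_period = unname(cf["tp"]))
  acf_res
}

bin_of <- function(lags) if (length(lags) > 1) lags[2] - lags[1] else 15

#' Sorted MUA distribution and percent silence
#'
#' @param mua numeric MUA trace (raw counts).
#' @return List with `sorted` (values sorted ascending) and `pct_silence`
#'   (percentage of bins with zero spikes).
#' @export
sorted_mua_and_silence <- function(mua) {
  mua <- as.numeric(mua)
  stopifnot(length(mua) > 0)
  list(sorted = sort(mua), pct_silence = 100 * mean(mua == 0))
}

#' Mean pairwise correlation of binned spike counts
#'
#' Pearson correlation of every unordered neuron pair, averaged. Neurons
#' with zero count variance are excluded (their correlation is undefined);
#' the number excluded is attached as an attribute.
#'
#' @param raster a [spike_raster()] at the analysis bin width (15 ms).
#' @return Scalar mean correlation with attribute `n_excluded`.
#' @export
mean_pairwise_correlation <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  x <- t(raster$counts)
  v <- apply(x, 2, stats::var)
  keep <- which(v > 0)
  if (length(keep) < 2)
    stop("degenerate input: fewer than 2 neurons with nonzero variance")
  cm <- stats::cor(x[, keep, drop = FALSE])
  val <- mean(cm[upper.tri(cm)])
  attr(val, "n_excluded") <- raster$n_neurons - length(keep)
  val
}

#' Subsample neurons from a raster
#'
#' Statistics of simulated networks are computed on a random 50-neuron
#' subsample to replicate the small-sample bias of ~50-neuron recordings.
#'
#' @param raster a [spike_raster()].
#' @param k number of neurons to keep.
#' @param seed integer seed.
#' @return A [spike_raster()] with `k` rows.
#' @export
subsample_neurons <- function(raster, k = 50L, seed = 1L) {
  stopifnot(inherits(raster, "spike_raster"))
  if (k > raster$n_neurons)
    stop("invalid argument: k exceeds the number of neurons")
  if (k == raster$n_neurons) return(raster)
  set.seed(seed)
  idx <- sort(sample.int(raster$n_neurons, k))
  spike_raster(raster$counts[idx, , drop = FALSE], raster$bin_ms)
}

#' All summary statistics of a raster
#'
#' The three fitted statistics (mean pairwise correlation, sorted MUA
#' distribution, MUA autocorrelation with its envelope fit) plus
#' descriptive extras (mean rate, percent silence).
#'
#' @param raster a [spike_raster()] (already subsampled if desired).
#' @param max_lag_ms largest ACF lag.
#' @param n_rank_bins number of rank bins the sorted MUA is resampled to
#'   (quantile grid), so rasters of different lengths are comparable.
#' @param highpass if `TRUE`, high-pass the MUA at 1 Hz before the ACF
#'   (awake-recording convention).
#' @param fit_envelope if `FALSE`, skip the parametric ACF fit (faster for
#'   grid caching).
#' @return An object of class `aqif_stats`: list with `mean_rate`
#'   (spikes/s/neuron), `mean_pairwise_corr`, `sorted_mua` (length
#'   `n_rank_bins`), `pct_silence`, `acf` (an `acf_result`).
#' @export
summary_stats <- function(raster, max_lag_ms = 600, n_rank_bins = 100L,
                          highpass = FALSE, fit_envelope = TRUE) {
  stopifnot(inherits(raster, "spike_raster"))
  mua <- compute_mua(raster, raster$bin_ms)
  sm <- sorted_mua_and_silence(mua)
  mua_for_acf <- if (highpass) highpass_mua(mua) else mua
  # a silent or constant trace has no defined ACF; represent it as the
  # zero-correlation ACF so such parameter points still receive a (large)
  # finite cost instead of poisoning the fit
  acf_res <- tryCatch(mua_acf(mua_for_acf, max_lag_ms), error = function(e) {
    n_lags <- as.integer(floor(max_lag_ms / raster$bin_ms))
    structure(list(lags_ms = (0:n_lags) * raster$bin_ms,
                   acf = c(1, rep(0, n_lags)),
                   fit = c(a = NA_real_, T_decay = NA_real_,
                           t_period = NA_real_), degenerate = TRUE),
              class = "acf_result")
  })
  if (!is.null(acf_res) && fit_envelope)
    acf_res <- tryCatch(fit_acf_envelope(acf_res), error = function(e) acf_res)
  mc <- tryCatch(as.numeric(mean_pairwise_correlation(raster)),
                 error = function(e) NA_real_)
  qs <- stats::quantile(sm$sorted, probs = seq(0, 1, length.out = n_rank_bins),
                        names = FALSE, type = 4)
  structure(list(
    mean_rate = sum(raster$counts) / raster$n_neurons / raster$duration_s,
    mean_pairwise_corr = mc,
    sorted_mua = qs,
    pct_silence = sm$pct_silence,
    acf = acf_res), class = "aqif_stats")
}

#' @export
print.aqif_stats <- function(x, ...) {
  cat(sprintf(paste0("aqif_stats: rate %.2f sp/s/neuron, corr %.3f, ",
                     "silence %.1f%%, ACF decay %.0f ms\n"),
              x$mean_rate, x$mean_pairwise_corr, x$pct_silence,
              if (!is.null(x$acf)) x$acf$fit[["T_decay"]] else NA))
  invisible(x)
}

#' Noise correlations across repeated trials
#'
#' Two estimators of trial-to-trial correlated variability. The residual
#' method subtracts each neuron's trial-averaged response (its PSTH) from
#' every trial and correlates the residuals. The shuffle method computes
#' the total correlation of the actual responses minus the signal
#' correlation, where the signal correlation is estimated after shuffling
#' the order of repeated trials independently for each time bin (averaged
#' over `n_shuffles` shuffles).
#'
#' @param trials a 3-d array `trial x neuron x bin` of spike counts in
#'   15 ms bins.
#' @param method `"residual"` or `"shuffle"`.
#' @param n_shuffles shuffle repetitions for the shuffle method.
#' @param seed seed for the shuffles.
#' @param pearson if `TRUE` (default) normalize to correlations; otherwise
#'   return raw covariances.
#' @return List of class `noise_corr` with `c_ij` (neuron x neuron matrix,
#'   unit diagonal), `mean_noise_corr` (mean over unordered pairs) and
#'   `method`.
#' @export
noise_correlations <- function(trials, method = c("residual", "shuffle"),
                               n_shuffles = 100L, seed = 1L, pearson = TRUE) {
  method <- match.arg(method)
  stopifnot(length(dim(trials)) == 3)
  n_tr <- dim(trials)[1]; n_nr <- dim(trials)[2]; n_bin <- dim(trials)[3]
  if (n_tr < 2) stop("invalid argument: need at least 2 trials")
  # neurons as columns, stacked trial-by-trial samples as rows
  flat <- function(a) {
    m <- aperm(a, c(3, 1, 2))          # bin, trial, neuron
    dim(m) <- c(n_bin * n_tr, n_nr)
    m
  }
  if (method == "residual") {
    psth <- apply(trials, c(2, 3), mean)             # neuron x bin
    resid <- sweep(trials, c(2, 3), psth, "-")
    x <- flat(resid)
    cij <- safe_cor(x, pearson)
  } else {
    x <- flat(trials)
    total <- safe_cor(x, pearson)
    set.seed(seed)
    sig <- matrix(0, n_nr, n_nr)
    for (s in seq_len(n_shuffles)) {
      # shuffling the trial order independently for each neuron and time
      # bin preserves every PSTH but breaks trial-to-trial alignment, so
      # the correlation of the shuffled data is the signal correlation
      sh <- trials
      for (nr in seq_len(n_nr)) for (bn in seq_len(n_bin))
        sh[, nr, bn] <- trials[sample.int(n_tr), nr, bn]
      sig <- sig + safe_cor(flat(sh), pearson)
    }
    sig <- sig / n_shuffles
    cij <- total - sig
    diag(cij) <- 1
  }
  pairs <- upper.tri(cij)
  structure(list(c_ij = cij,
                 mean_noise_corr = mean(cij[pairs], na.rm = TRUE),
                 method = method), class = "noise_corr")
}

safe_cor <- function(x, pearson) {
  if (pearson) {
    sds <- apply(x, 2, stats::sd)
    ok <- sds > 0
    cm <- matrix(NA_real_, ncol(x), ncol(x))
    if (sum(ok) >= 2) cm[ok, ok] <- stats::cor(x[, ok, drop = FALSE])
    diag(cm) <- 1
    cm
  } else {
    stats::cov(x)
  }
}
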