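# Small analysis helpers for recovering motion statistics from simulated
# trajectories.

#' Exponential decorrelation time of a time series
#'
#' Computes the sample autocorrelation up to `max_lag_s` and fits a decaying
#' exponential by least squares on the log-autocorrelation, restricted to
#' lags where the autocorrelation exceeds `floor` (log-linear fits blow up
#' on noisy near-zero tail values).
#'
#' @param x Time series sampled at interval `dt`.
#' @param dt Sampling interval (s).
#' @param max_lag_s Maximum lag considered (s).
#' @param floor Autocorrelation floor below which lags are discarded.
#' @return Fitted timescale (s).
#' @export
fit_decorrelation_time <- function(x, dt, max_lag_s, floor = 0.2) {
  L <- round(max_lag_s / dt)
  ac <- stats::acf(x, lag.max = L, plot = FALSE)$acf[-1]
  lags <- seq_len(L) * dt
  keep <- ac > floor
  if (any(!keep)) keep[min(which(!keep)):L] <- FALSE
  if (sum(keep) < 3) stop("autocorrelation decays too fast for this window")
  -1 / stats::coef(stats::lm(log(ac[keep]) ~ lags[keep]))[[2]]
}

#' Maximum-likelihood Rayleigh scale of a speed sample
#'
#' The ML estimator of the Rayleigh scale is
#' `sigma_hat = sqrt(mean(v^2) / 2)`.
#'
#' @param speeds Non-negative speed sample (m/s).
#' @return Estimated scale (m/s).
#' @export
fit_rayleigh_scale <- function(speeds) sqrt(mean(speeds^2) / 2)
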