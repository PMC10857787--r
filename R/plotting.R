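# Thin base-graphics helpers for quick visual inspection. These are
# convenience functions only; nothing in the package depends on them.

#' Plot an agent trajectory
#' @param agent An [Agent] with recorded history (see [simulate_agent]).
#' @param ... Passed to [plot].
#' @export
plot_trajectory <- function(agent, ...) {
  h <- agent$history
  if (is.null(h)) stop("agent has no recorded history")
  if (agent$env$dimensionality == "1D") {
    plot(h$t, h$x, type = "l", xlab = "time (s)", ylab = "x (m)", ...)
    return(invisible(NULL))
  }
  ext <- env_extent(agent$env)
  plot(h$x, h$y, type = "l", asp = 1, xlim = c(0, ext[1]),
       ylim = c(0, ext[2]), xlab = "x (m)", ylab = "y (m)", col = "grey30",
       ...)
  w <- .collision_walls(agent$env)
  if (nrow(w)) segments(w[, 1], w[, 2], w[, 3], w[, 4], lwd = 2)
  invisible(NULL)
}

#' Plot one cell of a rate map
#' @param rm A `RateMap` (see [explicit_rate_map]).
#' @param cell Cell index.
#' @param ... Passed to [image] / [plot].
#' @export
plot_rate_map <- function(rm, cell = 1, ...) {
  if (is.null(rm$y)) {
    plot(rm$x, rm$rates[, cell], type = "l", xlab = "x (m)",
         ylab = "rate (Hz)", ...)
  } else {
    image(rm$x, rm$y, ratemap_matrix(rm, cell), asp = 1, xlab = "x (m)",
          ylab = "y (m)", ...)
  }
  invisible(NULL)
}

#' Plot firing-rate time series
#' @param times Time vector (s).
#' @param rates Steps x cells rate matrix.
#' @param cells Which cells to draw.
#' @export
plot_rate_timeseries <- function(times, rates, cells = seq_len(min(5, ncol(rates)))) {
  matplot(times, rates[, cells, drop = FALSE], type = "l", lty = 1,
          xlab = "time (s)", ylab = "rate (Hz)")
  invisible(NULL)
}

#' Spike raster plot
#' @param times Time vector (s).
#' @param spikes Steps x cells 0/1 spike matrix.
#' @export
plot_spike_raster <- function(times, spikes) {
  idx <- which(spikes == 1, arr.ind = TRUE)
  plot(times[idx[, 1]], idx[, 2], pch = "|", cex = 0.6,
       xlab = "time (s)", ylab = "cell", ylim = c(0.5, ncol(spikes) + 0.5))
  invisible(NULL)
}

#' Diagram of a field-of-view tiling
#' @param tunings A tuning data.frame from [build_field_of_view].
#' @export
plot_field_of_view <- function(tunings) {
  x <- tunings$d * cos(tunings$phi + pi / 2)  # forward = up
  y <- tunings$d * sin(tunings$phi + pi / 2)
  plot(x, y, asp = 1, cex = 30 * tunings$sigma_d, xlab = "x (m)",
       ylab = "y (m)")
  invisible(NULL)
}
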