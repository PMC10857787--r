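# Fixture generators: canned environments and analytic trajectories with
# known ground truth, so every module is testable without external data.

#' Canned test environments
#'
#' Parameter-free arenas used across examples and tests: `"open_box"` (unit
#' square), `"one_wall"` (unit square with a wall from (0.5, 0) to
#' (0.5, 0.6)), `"hole_arena"` (unit square with a square hole in the
#' middle), `"periodic_box"` (unit square with periodic boundaries) and
#' `"1d_loop"` (1 m periodic line).
#'
#' @param kind One of the names above.
#' @return An [Arena].
#' @export
fixture_environment <- function(kind = c("open_box", "one_wall",
                                         "hole_arena", "periodic_box",
                                         "1d_loop")) {
  kind <- match.arg(kind)
  switch(kind,
    open_box = Arena(),
    one_wall = add_wall(Arena(), rbind(c(0.5, 0), c(0.5, 0.6))),
    hole_arena = add_hole(Arena(), rbind(c(0.4, 0.4), c(0.6, 0.4),
                                         c(0.6, 0.6), c(0.4, 0.6))),
    periodic_box = Arena(boundary_conditions = "periodic"),
    `1d_loop` = Arena(dimensionality = "1D",
                      boundary_conditions = "periodic"))
}

#' Analytic synthetic trajectories
#'
#' Smooth paths with a closed-form position function, staying inside the
#' unit box: `"circle"` (radius 0.3 around the centre, period 20 s),
#' `"lissajous"` (incommensurate frequencies, so the path fills the box) and
#' `"piecewise_linear"` (a triangle circuit at constant speed). Used as
#' ground truth for spline-upsampling error measurements.
#'
#' @param kind Trajectory family.
#' @param duration Duration (s).
#' @return A list with `fn(t)` returning an m x 2 position matrix,
#'   `duration`, and `scale` (the path's spatial scale, m).
#' @export
synthetic_trajectory <- function(kind = c("circle", "lissajous",
                                          "piecewise_linear"),
                                 duration = 60) {
  kind <- match.arg(kind)
  fn <- switch(kind,
    circle = function(t) cbind(0.5 + 0.3 * cos(2 * pi * t / 20),
                               0.5 + 0.3 * sin(2 * pi * t / 20)),
    lissajous = function(t) cbind(0.5 + 0.35 * sin(2 * pi * t / 23),
                                  0.5 + 0.35 * sin(2 * pi * t / 31 + 1)),
    piecewise_linear = function(t) {
      verts <- rbind(c(0.2, 0.2), c(0.8, 0.2), c(0.5, 0.8), c(0.2, 0.2))
      seg_len <- sqrt(rowSums(diff(verts)^2))
      total <- sum(seg_len)
      s <- (t %% 30) / 30 * total  # one lap per 30 s
      cum <- c(0, cumsum(seg_len))
      out <- matrix(NA_real_, length(s), 2)
      for (k in seq_along(seg_len)) {
        in_seg <- s >= cum[k] & s <= cum[k + 1]
        frac <- (s[in_seg] - cum[k]) / seg_len[k]
        out[in_seg, ] <- cbind(
          verts[k, 1] + frac * (verts[k + 1, 1] - verts[k, 1]),
          verts[k, 2] + frac * (verts[k + 1, 2] - verts[k, 2]))
      }
      out
    })
  list(fn = fn, duration = duration, scale = 1.0, kind = kind)
}

#' Sample a synthetic trajectory at a low rate
#'
#' @param truth A [synthetic_trajectory] result.
#' @param rate Sampling rate (Hz).
#' @return A list with `times` and `positions` suitable for
#'   [import_trajectory]; the ground truth is retained in `truth`.
#' @export
sample_low_rate_trajectory <- function(truth, rate) {
  if (rate <= 0) stop("`rate` must be positive")
  times <- seq(0, truth$duration, by = 1 / rate)
  list(times = times, positions = truth$fn(times), truth = truth)
}
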