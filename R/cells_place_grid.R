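# Place cells (five response profiles, wall-aware distance geometry) and
# grid cells (rectified / shifted sums of three plane-wave cosines at 60 deg).

# Default place-field centres: candidate points on a uniform grid spanning
# the arena, jittered by up to half the grid pitch, so coverage is even but
# looks random. Seed-dependent via the session RNG.
.default_centres <- function(env, n) {
  if (env$dimensionality == "1D") {
    pitch <- env$scale / n
    x <- (seq_len(n) - 0.5) * pitch + stats::runif(n, -pitch / 2, pitch / 2)
    return(matrix(pmin(pmax(x, 0), env$scale), ncol = 1))
  }
  ext <- env_extent(env)
  k <- ceiling(sqrt(n))
  gx <- (rep(seq_len(k), k) - 0.5) * ext[1] / k
  gy <- (rep(seq_len(k), each = k) - 0.5) * ext[2] / k
  keep <- sample.int(k * k, n)
  px <- gx[keep] + stats::runif(n, -ext[1] / (2 * k), ext[1] / (2 * k))
  py <- gy[keep] + stats::runif(n, -ext[2] / (2 * k), ext[2] / (2 * k))
  p <- cbind(pmin(pmax(px, 1e-6), ext[1] - 1e-6),
             pmin(pmax(py, 1e-6), ext[2] - 1e-6))
  # nudge any centre that landed inside a hole back to a valid draw
  bad <- !is_inside(env, p)
  while (any(bad)) {
    p[bad, 1] <- stats::runif(sum(bad), 0, ext[1])
    p[bad, 2] <- stats::runif(sum(bad), 0, ext[2])
    bad <- !is_inside(env, p)
  }
  p
}

#' Place cell population
#'
#' Each cell fires as a function of the environmental distance `d_i` from the
#' agent to its field centre. Five response profiles are provided:
#' `"gaussian"` `exp(-d^2 / 2w^2)`; `"gaussian_threshold"` (a Gaussian
#' cropped and levelled at one standard deviation, so exactly 0 at `d = w`);
#' `"diff_of_gaussians"` (centre-surround with ratio `r = 1.5` and zero total
#' volume); `"top_hat"` (1 within radius `w`); and `"one_hot"` (only the
#' closest cell fires). The distance respects walls according to
#' `wall_geometry`: `"geodesic"` (default; fields wrap smoothly around
#' walls), `"line_of_sight"` (rate 0 when a wall blocks the view of the
#' centre) or `"euclidean"` (fields bleed through walls).
#'
#' @param env An [Arena].
#' @param n Number of cells.
#' @param widths Field width parameter `w` (m), scalar or length-n.
#' @param centres Optional n x d matrix of field centres; default a jittered
#'   grid covering the arena evenly.
#' @param response One of `"gaussian"`, `"gaussian_threshold"`,
#'   `"diff_of_gaussians"`, `"top_hat"`, `"one_hot"`.
#' @param wall_geometry One of `"geodesic"`, `"line_of_sight"`,
#'   `"euclidean"`.
#' @param max_fr,min_fr Firing-rate scaling (Hz).
#' @param noise_std,noise_coherence_time Additive OU rate noise (Hz, s).
#' @param name Population label.
#' @return A population of class `c("PlaceCells", "Neurons")`.
#' @export
PlaceCells <- function(env, n = 10, widths = 0.2, centres = NULL,
                       response = c("gaussian", "gaussian_threshold",
                                    "diff_of_gaussians", "top_hat", "one_hot"),
                       wall_geometry = c("geodesic", "line_of_sight",
                                         "euclidean"),
                       max_fr = 1, min_fr = 0, noise_std = 0,
                       noise_coherence_time = 0.5, name = "PlaceCells") {
  response <- match.arg(response)
  wall_geometry <- match.arg(wall_geometry)
  if (is.null(centres)) centres <- .default_centres(env, n)
  centres <- .as_points(centres)
  if (nrow(centres) != n) stop("`centres` must have n rows")
  if (!all(is_inside(env, centres))) stop("centres must lie inside the arena")
  widths <- rep_len(widths, n)
  if (any(widths <= 0)) stop("`widths` must be positive")
  pop <- .neurons_base(env, n, name, max_fr, min_fr, noise_std,
                       noise_coherence_time)
  pop$centres <- centres
  pop$widths <- widths
  pop$response <- response
  pop$wall_geometry <- wall_geometry
  class(pop) <- c("PlaceCells", "Neurons")
  pop
}

# Distance from every query position to every centre (m x n), under the
# population's wall geometry.
.centre_distances <- function(pop, pos) {
  n <- nrow(pop$centres)
  D <- matrix(NA_real_, nrow(pos), n)
  for (i in seq_len(n))
    D[, i] <- env_distance(pop$env, pop$centres[i, ], pos,
                           geometry = pop$wall_geometry)
  D
}

.place_response <- function(D, widths, response) {
  W <- matrix(widths, nrow(D), length(widths), byrow = TRUE)
  switch(response,
    gaussian = exp(-D^2 / (2 * W^2)),
    gaussian_threshold = {
      g <- (exp(-D^2 / (2 * W^2)) - exp(-1 / 2)) / (1 - exp(-1 / 2))
      pmax(g, 0)
    },
    diff_of_gaussians = {
      r <- 1.5
      (exp(-D^2 / (2 * W^2)) - (1 / r^2) * exp(-D^2 / (2 * (r * W)^2))) /
        (1 - 1 / r^2)
    },
    top_hat = (D <= W) * 1,
    one_hot = {
      out <- matrix(0, nrow(D), ncol(D))
      win <- max.col(-D, ties.method = "first")
      out[cbind(seq_len(nrow(D)), win)] <- 1
      out
    })
}

#' @export
raw_rates.PlaceCells <- function(pop, state, ...) {
  D <- .centre_distances(pop, state$pos)
  R <- .place_response(D, pop$widths, pop$response)
  R[!is.finite(D) & pop$response != "one_hot"] <- 0  # blocked line of sight
  R
}

#' Grid cell population
#'
#' Each cell's firing is the thresholded (or shifted) sum of three
#' plane-wave cosines with wave directions 60 degrees apart:
#' rectified variant `(1/3) * max(0, sum cos)`, shifted variant
#' `(2/3) * ((1/3) * sum cos + 1/2)` (softer fields). Grid scales,
#' orientations and phase offsets are sampled uniformly at initialisation
#' unless provided.
#'
#' @param env An [Arena] (2D).
#' @param n Number of cells.
#' @param gridscale Either a length-n vector of grid scales (m) or a range
#'   `c(min, max)` to sample uniformly (default `c(0.5, 1)`).
#' @param orientation Length-n wave directions (rad) or a sampling range
#'   (default `c(0, 2*pi)`).
#' @param phase_offset Length-n phase offsets (rad) or a sampling range
#'   (default `c(0, 2*pi)`).
#' @param response `"three_rectified_cosines"` (default) or
#'   `"three_shifted_cosines"`.
#' @inheritParams PlaceCells
#' @return A population of class `c("GridCells", "Neurons")`.
#' @export
GridCells <- function(env, n = 10, gridscale = c(0.5, 1),
                      orientation = c(0, 2 * pi),
                      phase_offset = c(0, 2 * pi),
                      response = c("three_rectified_cosines",
                                   "three_shifted_cosines"),
                      max_fr = 1, min_fr = 0, noise_std = 0,
                      noise_coherence_time = 0.5, name = "GridCells") {
  stopifnot(env$dimensionality == "2D")
  response <- match.arg(response)
  samp <- function(par, lo_hi_ok = TRUE) {
    if (length(par) == n && n != 2) return(par)
    if (length(par) == 2) return(stats::runif(n, par[1], par[2]))
    rep_len(par, n)
  }
  gridscale <- samp(gridscale)
  orientation <- samp(orientation)
  phase_offset <- samp(phase_offset)
  if (any(gridscale <= 0)) stop("grid scales must be positive")
  pop <- .neurons_base(env, n, name, max_fr, min_fr, noise_std,
                       noise_coherence_time)
  pop$gridscale <- gridscale
  pop$orientation <- orientation
  pop$phase_offset <- phase_offset
  pop$response <- response
  class(pop) <- c("GridCells", "Neurons")
  pop
}

#' @export
raw_rates.GridCells <- function(pop, state, ...) {
  pos <- state$pos
  m <- nrow(pos)
  R <- matrix(0, m, pop$n)
  for (i in seq_len(pop$n)) {
    s <- 0
    for (a in c(0, pi / 3, 2 * pi / 3)) {
      th <- pop$orientation[i] + a
      proj <- pos[, 1] * cos(th) + pos[, 2] * sin(th)
      s <- s + cos(2 * pi * proj / pop$gridscale[i] + pop$phase_offset[i])
    }
    # With a shared scalar phase offset the shifted sum can dip below zero
    # (the minimum of three 60-degree cosines is -3/2 only at zero phase),
    # so it is clamped to keep pre-scaled rates in [0, 1].
    R[, i] <- if (pop$response == "three_rectified_cosines")
      pmax(0, s) / 3 else pmax(0, (2 / 3) * (s / 3 + 1 / 2))
  }
  R
}
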