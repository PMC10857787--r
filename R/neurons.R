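# Neuron population base contract: every population computes raw (pre-scaled,
# in [0,1] for the analytic models) rates from an agent state, which are then
# linearly scaled to [f_min, f_max], optionally perturbed by smooth OU noise,
# recorded, and used to draw Bernoulli-per-step spikes.

# Shared fields for all populations. `scale` = FALSE for function-approximator
# layers whose outputs are unconstrained reals and bypass min/max scaling.
.neurons_base <- function(env, n, name, max_fr = 1, min_fr = 0,
                          noise_std = 0, noise_coherence_time = 0.5,
                          scale = TRUE) {
  if (min_fr > max_fr) stop("`min_fr` must be <= `max_fr`")
  if (n < 1) stop("`n` must be >= 1")
  list(env = env, n = as.integer(n), name = name,
       max_fr = max_fr, min_fr = min_fr,
       noise_std = noise_std, noise_coherence_time = noise_coherence_time,
       scale = scale,
       noise = numeric(n), rates = numeric(n), spikes = integer(n), t = 0)
}

#' Raw (pre-scaling) firing rates of a population
#'
#' S3 generic dispatched on the population class. `state` is a list with
#' `pos` (an m x d matrix of positions -- methods are vectorised over rows),
#' and optionally `vel`, `head` and `t`. Analytic cell models return values
#' in `[0, 1]` (documented exceptions: object vector cells with several
#' nearby matching objects, and the theta modulation factor of
#' phase-precessing place cells).
#'
#' @param pop A neuron population.
#' @param state An agent-state list, e.g. from [agent_state].
#' @param ... Method-specific arguments.
#' @return An m x n matrix of rates.
#' @export
raw_rates <- function(pop, state, ...) UseMethod("raw_rates")

#' Linear min/max scaling of raw rates
#'
#' `F <- (f_max - f_min) * F + f_min`, an order-preserving affine map taking
#' raw rates in `[0, 1]` to firing rates in `[f_min, f_max]` Hz.
#'
#' @param raw Raw rates.
#' @param f_min,f_max Minimum and maximum firing rates (Hz).
#' @return Scaled rates (Hz).
#' @export
scale_rates <- function(raw, f_min, f_max) (f_max - f_min) * raw + f_min

#' Bernoulli-per-step spike sampling
#'
#' Each cell spikes independently with probability `F_i * dt` in a step
#' (at most one spike per cell per step). Negative rates are clipped to 0
#' before sampling; probabilities above 1 are clipped with a warning.
#'
#' @param rates Firing rates (Hz).
#' @param dt Time step (s).
#' @return Integer 0/1 vector of spikes.
#' @export
sample_spikes <- function(rates, dt) {
  p <- pmax(rates, 0) * dt
  if (any(p > 1)) {
    warning("spike probability F * dt > 1; clipping to 1")
    p <- pmin(p, 1)
  }
  as.integer(stats::runif(length(p)) < p)
}

#' Advance a population by one timestep
#'
#' Fixed pipeline: raw model rate -> min/max scaling -> additive OU noise ->
#' record -> spike sampling. Stored rates keep the (possibly negative) noisy
#' value; clipping to zero happens only for spike sampling, so noise
#' statistics remain testable.
#'
#' @param pop A neuron population.
#' @param agent An [Agent] (or an [agent_state] list).
#' @param dt Time step (s).
#' @param ... Passed to [raw_rates] (e.g. `input_rates` for
#'   function-approximator layers).
#' @return The updated population with `$rates` and `$spikes` set.
#' @export
update_neurons <- function(pop, agent, dt, ...) UseMethod("update_neurons")

#' @export
update_neurons.default <- function(pop, agent, dt, ...) {
  state <- if (inherits(agent, "Agent")) agent_state(agent) else agent
  raw <- drop(raw_rates(pop, state, ...))
  r <- if (isTRUE(pop$scale)) scale_rates(raw, pop$min_fr, pop$max_fr) else raw
  if (pop$noise_std > 0) {
    pop$noise <- ou_step(pop$noise, dt, pop$noise_coherence_time,
                         pop$noise_std, 0)
    r <- r + pop$noise
  }
  pop$rates <- as.numeric(r)
  pop$spikes <- sample_spikes(pop$rates, dt)
  pop$t <- state$t
  pop
}

# Grid of bin-centre positions at spacing dx covering the arena.
.ratemap_grid <- function(env, dx) {
  if (env$dimensionality == "1D") {
    x <- seq(dx / 2, env$scale - dx / 2, by = dx)
    return(list(x = x, y = NULL, pos = matrix(x, ncol = 1)))
  }
  ext <- env_extent(env)
  x <- seq(dx / 2, ext[1] - dx / 2, by = dx)
  y <- seq(dx / 2, ext[2] - dx / 2, by = dx)
  g <- expand.grid(x = x, y = y)
  list(x = x, y = y, pos = as.matrix(g))
}

#' Explicit (analytic) rate map
#'
#' Evaluates the population's raw rate function over a grid of spacing `dx`.
#' Motion-dependent cells (velocity, head-direction, egocentric vector cells)
#' are evaluated at a stated reference state: heading `reference_heading`
#' (default +x) and speed `reference_speed` (default the agent speed scale
#' 0.08 m/s).
#'
#' @param pop A neuron population.
#' @param dx Grid spacing (m); defaults to the arena's `dx`.
#' @param reference_heading Unit head-direction vector used for
#'   direction-dependent cells.
#' @param reference_speed Speed (m/s) used for velocity-dependent cells.
#' @return A `RateMap`: list with `x`, `y`, `rates` (matrix, grid points x
#'   cells; raw, pre-scaling), `dx` and `kind = "explicit"`. Grid points
#'   outside the arena (inside holes) are `NA`.
#' @export
explicit_rate_map <- function(pop, dx = NULL, reference_heading = c(1, 0),
                              reference_speed = 0.08) {
  env <- pop$env
  if (is.null(dx)) dx <- env$dx
  g <- .ratemap_grid(env, dx)
  state <- list(pos = g$pos,
                vel = reference_speed * reference_heading,
                head = reference_heading, t = 0)
  R <- raw_rates(pop, state)
  R <- matrix(R, nrow = nrow(g$pos))
  inside <- is_inside(env, g$pos)
  R[!inside, ] <- NA_real_
  structure(list(x = g$x, y = g$y, rates = R, dx = dx, n = pop$n,
                 kind = "explicit"), class = "RateMap")
}

#' Empirical (occupancy-weighted) rate map
#'
#' The continuous analogue of a smoothed spike raster: a histogram of visited
#' positions weighted by observed firing rates, divided by the occupancy
#' histogram, both Gaussian-smoothed. Bins never visited are `NA`, not 0.
#'
#' @param positions m x 2 matrix (or m-vector in 1D) of visited positions.
#' @param rates m-vector (one cell) or m x n matrix of observed rates.
#' @param env The [Arena].
#' @param dx Bin width (m); defaults to the arena's `dx`.
#' @param sigma_smooth Gaussian smoothing width (m); default `5 * dx`.
#' @return A `RateMap` with `kind = "empirical"`.
#' @export
empirical_rate_map <- function(positions, rates, env, dx = NULL,
                               sigma_smooth = NULL) {
  if (is.null(dx)) dx <- env$dx
  if (is.null(sigma_smooth)) sigma_smooth <- 5 * dx
  positions <- .as_points(positions)
  rates <- if (is.null(dim(rates))) matrix(rates, ncol = 1) else as.matrix(rates)
  g <- .ratemap_grid(env, dx)
  if (env$dimensionality == "1D") {
    ix <- pmin(pmax(findInterval(positions[, 1], seq(0, env$scale, by = dx),
                                 all.inside = TRUE), 1), length(g$x))
    occ <- tabulate(ix, nbins = length(g$x))
    R <- sapply(seq_len(ncol(rates)), function(k) {
      w <- as.numeric(tapply(rates[, k], factor(ix, levels = seq_along(g$x)),
                             sum, default = 0))
      ws <- .gauss_smooth_1d(w, sigma_smooth / dx)
      os <- .gauss_smooth_1d(occ, sigma_smooth / dx)
      out <- ws / os
      out[occ == 0] <- NA_real_
      out
    })
    return(structure(list(x = g$x, y = NULL, rates = R, dx = dx,
                          n = ncol(rates), kind = "empirical"),
                     class = "RateMap"))
  }
  nx <- length(g$x); ny <- length(g$y)
  ix <- pmin(pmax(ceiling(positions[, 1] / dx), 1), nx)
  iy <- pmin(pmax(ceiling(positions[, 2] / dx), 1), ny)
  bin <- (iy - 1) * nx + ix
  occ <- tabulate(bin, nbins = nx * ny)
  occ_m <- matrix(occ, nx, ny)
  occ_s <- .gauss_smooth_2d(occ_m, sigma_smooth / dx)
  R <- sapply(seq_len(ncol(rates)), function(k) {
    w <- as.numeric(tapply(rates[, k], factor(bin, levels = seq_len(nx * ny)),
                           sum, default = 0))
    w[is.na(w)] <- 0
    ws <- .gauss_smooth_2d(matrix(w, nx, ny), sigma_smooth / dx)
    out <- ws / occ_s
    out[occ_m == 0] <- NA_real_
    as.numeric(out)
  })
  structure(list(x = g$x, y = g$y, rates = R, dx = dx, n = ncol(rates),
                 kind = "empirical"), class = "RateMap")
}

.gauss_kernel <- function(sigma_bins) {
  if (sigma_bins <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_bins))
  k <- exp(-((-r):r)^2 / (2 * sigma_bins^2))
  k / sum(k)
}

.gauss_smooth_1d <- function(v, sigma_bins) {
  k <- .gauss_kernel(sigma_bins)
  if (length(k) == 1) return(v)
  r <- (length(k) - 1) / 2
  padded <- c(rep(0, r), v, rep(0, r))
  out <- stats::filter(padded, k, sides = 2)
  as.numeric(out[(r + 1):(r + length(v))])
}

# Separable 2D Gaussian smoothing (zero-padded).
.gauss_smooth_2d <- function(M, sigma_bins) {
  M1 <- apply(M, 2, .gauss_smooth_1d, sigma_bins = sigma_bins)
  t(apply(t(M1), 2, .gauss_smooth_1d, sigma_bins = sigma_bins))
}

#' Reshape one cell of a rate map into a matrix
#'
#' @param rm A `RateMap`.
#' @param cell Cell index.
#' @return For 2D maps, an `length(x)` x `length(y)` matrix; for 1D a vector.
#' @export
ratemap_matrix <- function(rm, cell = 1) {
  if (is.null(rm$y)) return(rm$rates[, cell])
  matrix(rm$rates[, cell], length(rm$x), length(rm$y))
}

#' @export
print.RateMap <- function(x, ...) {
  cat(sprintf("<RateMap (%s), %d cell(s), %s grid, dx = %g m>\n", x$kind,
              x$n, if (is.null(x$y)) length(x$x)
                   else paste(length(x$x), "x", length(x$y)), x$dx))
  invisible(x)
}
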