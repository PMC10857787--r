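# Random-foraging motion model: Ornstein-Uhlenbeck velocity processes with a
# Rayleigh speed transform, smooth wall repulsion with a tunable thigmotaxis
# bias, optional drift-velocity control and smoothed head direction.

#' One Euler-Maruyama step of an Ornstein-Uhlenbeck process
#'
#' The process is parameterised by its decoherence timescale `tau`, long-run
#' standard deviation `sigma` and long-run mean `mu`:
#' `x <- x + (mu - x) * dt / tau + sqrt(2 * sigma^2 / tau) * noise * sqrt(dt)`.
#' Statistics of the sampled paths are independent of `dt`, which is what
#' makes the motion model temporally continuous.
#'
#' @param value Current value(s) of the process (vectorised over independent
#'   processes).
#' @param dt Time step (s), must be positive.
#' @param tau Decoherence timescale (s).
#' @param sigma Long-run standard deviation.
#' @param mu Long-run mean (default 0).
#' @param noise Standard-normal draw(s), one per process; defaults to
#'   `rnorm(length(value))`.
#' @return Updated value(s).
#' @export
ou_step <- function(value, dt, tau, sigma, mu = 0,
                    noise = stats::rnorm(length(value))) {
  if (dt <= 0) stop("`dt` must be positive")
  if (tau <= 0) stop("`tau` must be positive")
  value + (mu - value) * dt / tau + sqrt(2 * sigma^2 / tau) * noise * sqrt(dt)
}

#' Map a standard-normal variable to a Rayleigh-distributed speed
#'
#' The monotone transform `R_sigma(x) = sigma * sqrt(-2 * log(1 - Phi(x)))`
#' pushes N(0,1) forward to a Rayleigh distribution of scale `sigma`. It is
#' applied to an OU process of unit variance so that simulated speeds are
#' Rayleigh distributed (as rodent running speeds are) while retaining the
#' OU decoherence timescale. The normal CDF is clipped to
#' `[1e-12, 1 - 1e-12]` before the log for numerical safety.
#'
#' @param x Standard-normal value(s).
#' @param sigma Rayleigh scale parameter (m/s).
#' @return Non-negative speed(s) (m/s), monotone increasing in `x`.
#' @export
rayleigh_transform <- function(x, sigma) {
  if (sigma <= 0) stop("`sigma` must be positive")
  p <- pmin(pmax(stats::pnorm(x), 1e-12), 1 - 1e-12)
  sigma * sqrt(-2 * log(1 - p))
}

#' Inverse of [rayleigh_transform]
#' @param v Speed(s) (m/s), non-negative.
#' @param sigma Rayleigh scale (m/s).
#' @return Standard-normal value(s).
#' @export
rayleigh_transform_inverse <- function(v, sigma) {
  p <- pmin(pmax(1 - exp(-v^2 / (2 * sigma^2)), 1e-12), 1 - 1e-12)
  stats::qnorm(p)
}

#' Construct an agent
#'
#' An `Agent` moves through an [Arena] under the random motion model (or an
#' imported trajectory; see [import_trajectory]). Default parameters are
#' those fitted to open-field rodent foraging: Rayleigh speed scale 0.08 m/s
#' decohering over 0.7 s, and normally distributed rotational velocity of
#' standard deviation 2*pi/3 rad/s decohering over 0.08 s.
#'
#' @param env An [Arena].
#' @param dt Default integration timestep (s).
#' @param speed_mean Rayleigh scale `sigma_v` of 2D speeds; in 1D the mean
#'   `mu_v` of the (normal) velocity distribution (m/s).
#' @param speed_std 1D only: standard deviation `sigma_v` of the velocity
#'   (m/s).
#' @param speed_coherence_time Decoherence timescale `tau_v` of linear speed
#'   (s).
#' @param rotational_velocity_std Standard deviation `sigma_omega` of
#'   rotational velocity (rad/s).
#' @param rotational_velocity_coherence_time Decoherence timescale
#'   `tau_omega` (s).
#' @param thigmotaxis Wall-following bias `lambda` in `[0, 1]`: 0 gives pure
#'   spring-like bouncing off walls, 1 gives pure conveyor-belt lingering.
#' @param wall_repel_distance Range of wall influence `d_wall` (m).
#' @param walls_repel_strength Unitless repulsion strength `s`; 0 disables
#'   wall repulsion entirely.
#' @param head_direction_smoothing Timescale `tau_h` (s) of the exponential
#'   smoothing turning velocity into head direction (2D; 1D uses the sign of
#'   the velocity with no smoothing).
#' @param drift_to_random_strength_ratio Ratio `k` controlling how strongly
#'   an externally supplied drift velocity dominates the random motion.
#' @param position Initial position; default uniform random inside the arena.
#' @param rng_seed Optional integer seed consumed at construction (initial
#'   position/velocity draws).
#' @return An object of class `"Agent"`.
#' @export
Agent <- function(env, dt = 0.01,
                  speed_mean = 0.08, speed_std = 0.08,
                  speed_coherence_time = 0.7,
                  rotational_velocity_std = 2 * pi / 3,
                  rotational_velocity_coherence_time = 0.08,
                  thigmotaxis = 0.5, wall_repel_distance = 0.1,
                  walls_repel_strength = 1.0,
                  head_direction_smoothing = 0.15,
                  drift_to_random_strength_ratio = 1.0,
                  position = NULL, rng_seed = NULL) {
  stopifnot(inherits(env, "Arena"))
  if (thigmotaxis < 0 || thigmotaxis > 1) stop("`thigmotaxis` must be in [0, 1]")
  if (walls_repel_strength < 0) stop("`walls_repel_strength` must be >= 0")
  if (!is.null(rng_seed)) set.seed(rng_seed)

  d2 <- env$dimensionality == "2D"
  if (is.null(position)) {
    position <- .random_position(env)
  }
  if (!all(is_inside(env, matrix(position, 1, ncol = if (d2) 2 else 1))))
    stop("initial position must lie inside the arena")

  if (d2) {
    z0 <- stats::rnorm(1)
    th0 <- stats::runif(1, 0, 2 * pi)
    v0 <- rayleigh_transform(z0, speed_mean) * c(cos(th0), sin(th0))
    state <- list(t = 0, position = position, velocity = v0,
                  head_direction = c(cos(th0), sin(th0)),
                  omega = 0, theta = th0)
  } else {
    v0 <- stats::rnorm(1, speed_mean, speed_std)
    state <- list(t = 0, position = position[1], velocity = v0,
                  head_direction = sign(v0 + (v0 == 0)))
  }

  structure(list(
    env = env, dt = dt,
    params = list(speed_mean = speed_mean, speed_std = speed_std,
                  speed_coherence_time = speed_coherence_time,
                  rotational_velocity_std = rotational_velocity_std,
                  rotational_velocity_coherence_time =
                    rotational_velocity_coherence_time,
                  thigmotaxis = thigmotaxis,
                  wall_repel_distance = wall_repel_distance,
                  walls_repel_strength = walls_repel_strength,
                  head_direction_smoothing = head_direction_smoothing,
                  drift_to_random_strength_ratio =
                    drift_to_random_strength_ratio),
    state = state, trajectory = NULL, history = NULL
  ), class = "Agent")
}

.random_position <- function(env) {
  if (env$dimensionality == "1D") return(stats::runif(1, 0, env$scale))
  ext <- env_extent(env)
  for (i in 1:1000) {
    p <- c(stats::runif(1, 0, ext[1]), stats::runif(1, 0, ext[2]))
    if (all(is_inside(env, matrix(p, 1)))) return(p)
  }
  stop("could not sample a position inside the arena")
}

#' @export
print.Agent <- function(x, ...) {
  cat(sprintf("<Agent in %s arena at t = %.2f s, position (%s)>\n",
              x$env$dimensionality, x$state$t,
              paste(signif(x$state$position, 4), collapse = ", ")))
  invisible(x)
}

#' Wall repulsion: spring deceleration and conveyor displacement
#'
#' For every wall within `d_wall` of the agent two effects apply, both zero
#' exactly at `d_wall` (continuous onset). A spring-like acceleration
#' `k1 * n * (s * sigma_v)^2 / d_wall^2 * (d_wall - d_perp)` decelerates the
#' internal velocity (tuned so that with `k1 = 1` a head-on approach at speed
#' `s * sigma_v` stops just before the wall). A conveyor-belt velocity
#' `k2 * n * s * sigma_v * (1 - sqrt(1 - (d_wall - d_perp)^2 / d_wall^2))`
#' displaces the position only, slowing the approach without turning the
#' agent -- the source of the thigmotactic lingering. The mixture is set by
#' the thigmotaxis parameter: `k1 = 3 * (1 - lambda)^2`, `k2 = 6 * lambda^2`.
#' Contributions from overlapping walls (e.g. corners) are summed.
#'
#' @param agent An [Agent] in a 2D arena.
#' @param dt Time step (s).
#' @return A list with `dv` (velocity increment over `dt`, m/s) and `dx`
#'   (position increment over `dt`, m).
#' @export
wall_interaction <- function(agent, dt) {
  p <- agent$params
  walls <- .collision_walls(agent$env)
  .wall_interaction_core(agent$state$position, walls, p, dt)
}

.wall_interaction_core <- function(pos, walls, p, dt) {
  zero <- list(dv = c(0, 0), dx = c(0, 0))
  if (p$walls_repel_strength == 0 || nrow(walls) == 0) return(zero)
  g <- .wall_geometry_at(pos, walls)
  act <- g$dist <= p$wall_repel_distance
  if (!any(act)) return(zero)
  k1 <- 3 * (1 - p$thigmotaxis)^2
  k2 <- 6 * p$thigmotaxis^2
  svs <- p$walls_repel_strength * p$speed_mean
  dwall <- p$wall_repel_distance
  pen <- dwall - g$dist[act]                       # penetration depth
  nrm <- g$normal[act, , drop = FALSE]
  spring <- k1 * svs^2 / dwall^2 * pen             # acceleration magnitudes
  belt <- k2 * svs * (1 - sqrt(pmax(0, 1 - pen^2 / dwall^2)))
  list(dv = c(sum(nrm[, 1] * spring), sum(nrm[, 2] * spring)) * dt,
       dx = c(sum(nrm[, 1] * belt), sum(nrm[, 2] * belt)) * dt)
}

#' Advance an agent by one timestep
#'
#' Applies the full 2D update: OU steps for rotational velocity and the
#' speed-driving variable, Rayleigh speed transform, rotation of the velocity
#' direction, optional relaxation toward a drift velocity, wall repulsion,
#' integration of position with elastic collision handling (or periodic
#' wrapping), and head-direction smoothing. In 1D the velocity itself is an
#' OU process and boundaries reflect (solid) or wrap (periodic).
#'
#' @param agent An [Agent].
#' @param dt Time step (s); defaults to `agent$dt`.
#' @param drift_velocity Optional externally imposed velocity toward which
#'   the agent's velocity relaxes with timescale `tau_v / k`.
#' @param drift_ratio Optional override of the agent's
#'   `drift_to_random_strength_ratio`.
#' @return The updated agent (history is not recorded; see [simulate_agent]).
#' @export
update_agent <- function(agent, dt = NULL, drift_velocity = NULL,
                         drift_ratio = NULL) {
  if (is.null(dt)) dt <- agent$dt
  if (dt <= 0) stop("`dt` must be positive")
  if (!is.null(agent$trajectory))
    return(.update_agent_imported(agent, dt))
  if (agent$env$dimensionality == "1D")
    return(.update_agent_1d(agent, dt))
  walls <- .collision_walls(agent$env)
  agent$state <- .step_2d(agent$state, agent$env, walls, agent$params, dt,
                          drift_velocity, drift_ratio)
  agent
}

# Core 2D step; operates on the bare state list for speed. The velocity
# vector is the persistent state: the rotational OU process rotates it and
# the speed OU process acts on the normal variable *re-derived from the
# current speed* each step, so wall- and collision-induced speed changes
# persist and relax back on the speed coherence timescale.
.step_2d <- function(st, env, walls, p, dt, drift_velocity = NULL,
                     drift_ratio = NULL) {
  tau_v <- p$speed_coherence_time
  v <- st$velocity
  # (i) rotational OU update; rotate the velocity direction
  st$omega <- ou_step(st$omega, dt, p$rotational_velocity_coherence_time,
                      p$rotational_velocity_std, 0)
  dth <- st$omega * dt
  v <- c(cos(dth) * v[1] - sin(dth) * v[2],
         sin(dth) * v[1] + cos(dth) * v[2])
  st$theta <- (st$theta + dth) %% (2 * pi)
  # (ii) speed OU update through the Rayleigh transform
  sp <- sqrt(sum(v^2))
  z <- rayleigh_transform_inverse(sp, p$speed_mean)
  z <- ou_step(z, dt, tau_v, 1, 0)
  speed <- rayleigh_transform(z, p$speed_mean)
  v <- if (sp > 0) v * (speed / sp)
       else speed * c(cos(st$theta), sin(st$theta))
  # (iii) drift-velocity control (applied after the random update); the
  # linear relaxation is integrated exactly over the step (gain
  # 1 - exp(-k*dt/tau_v), equal to (k/tau_v)*dt as dt -> 0), which stays
  # stable for arbitrarily strong drift ratios
  if (!is.null(drift_velocity)) {
    k <- if (is.null(drift_ratio)) p$drift_to_random_strength_ratio else drift_ratio
    v <- v + (1 - exp(-k * dt / tau_v)) * (drift_velocity - v)
  }
  # (iv) wall repulsion
  wi <- .wall_interaction_core(st$position, walls, p, dt)
  v <- v + wi$dv
  # (v) integrate position, handle collisions / wrapping
  prop <- st$position + v * dt + wi$dx
  hit <- .first_crossing(st$position, prop, walls)
  if (!is.null(hit)) {
    # elastic reflection: flip the normal component, reset speed to 0.5*sigma_v
    g <- .wall_geometry_at(st$position, walls[hit$wall, , drop = FALSE])
    n <- g$normal[1, ]
    v <- v - 2 * sum(v * n) * n
    sp <- sqrt(sum(v^2))
    if (sp > 0) v <- v * (0.5 * p$speed_mean / sp)
    # do not cross; stay at the pre-step position
  } else {
    st$position <- prop
    if (env$boundary_conditions == "periodic") {
      st$position <- wrap_position(env, st$position)
    } else {
      ext <- env_extent(env)
      st$position <- pmin(pmax(st$position, 1e-9), ext - 1e-9)
    }
  }
  st$velocity <- v
  st$theta <- atan2(v[2], v[1]) %% (2 * pi)
  # (viii) head direction: smoothed then normalised velocity
  sp <- sqrt(sum(v^2))
  if (sp > 0) {
    tau_h <- max(p$head_direction_smoothing, dt)
    h <- (1 - dt / tau_h) * st$head_direction + (dt / tau_h) * v / sp
    nh <- sqrt(sum(h^2))
    if (nh > 0) st$head_direction <- h / nh
  }
  st$t <- st$t + dt
  st
}

.update_agent_1d <- function(agent, dt) {
  p <- agent$params
  st <- agent$state
  st$velocity <- ou_step(st$velocity, dt, p$speed_coherence_time,
                         p$speed_std, p$speed_mean)
  x <- st$position + st$velocity * dt
  L <- agent$env$scale
  if (agent$env$boundary_conditions == "periodic") {
    x <- x %% L
  } else {
    if (x < 0) { x <- -x; st$velocity <- -st$velocity }
    if (x > L) { x <- 2 * L - x; st$velocity <- -st$velocity }
    x <- min(max(x, 0), L)
  }
  st$position <- x
  if (st$velocity != 0) st$head_direction <- sign(st$velocity)
  st$t <- st$t + dt
  agent$state <- st
  agent
}

#' Simulate an agent for a duration, recording history
#'
#' Runs the motion model for `duration / dt` steps with a preallocated
#' history. For 2D agents the returned history has columns
#' `t, x, y, vx, vy, speed, omega, hx, hy`; for 1D agents `t, x, v, h`.
#'
#' @param agent An [Agent].
#' @param duration Simulated time (s).
#' @param dt Time step (s); defaults to `agent$dt`.
#' @param drift_velocity_fn Optional `function(t, position, velocity)`
#'   returning a drift velocity for that step (2D only).
#' @param seed Optional integer seed set before the run.
#' @return The agent, with `$history` set to a data.frame.
#' @export
simulate_agent <- function(agent, duration, dt = NULL,
                           drift_velocity_fn = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dt)) dt <- agent$dt
  n <- round(duration / dt)
  if (!is.null(agent$trajectory))
    return(.simulate_imported(agent, n, dt))
  if (agent$env$dimensionality == "1D") {
    H <- matrix(NA_real_, n, 4, dimnames = list(NULL, c("t", "x", "v", "h")))
    for (i in seq_len(n)) {
      agent <- .update_agent_1d(agent, dt)
      st <- agent$state
      H[i, ] <- c(st$t, st$position, st$velocity, st$head_direction)
    }
    agent$history <- as.data.frame(H)
    return(agent)
  }
  env <- agent$env
  walls <- .collision_walls(env)
  p <- agent$params
  st <- agent$state
  H <- matrix(NA_real_, n, 9, dimnames = list(NULL, c(
    "t", "x", "y", "vx", "vy", "speed", "omega", "hx", "hy")))
  for (i in seq_len(n)) {
    dv <- if (is.null(drift_velocity_fn)) NULL
          else drift_velocity_fn(st$t, st$position, st$velocity)
    st <- .step_2d(st, env, walls, p, dt, dv)
    H[i, 1] <- st$t
    H[i, 2:3] <- st$position
    H[i, 4:5] <- st$velocity
    H[i, 6] <- sqrt(st$velocity[1]^2 + st$velocity[2]^2)
    H[i, 7] <- st$omega
    H[i, 8:9] <- st$head_direction
  }
  agent$state <- st
  agent$history <- as.data.frame(H)
  agent
}

# Snapshot of the agent state consumed by neuron populations.
#' Extract the state snapshot used by neuron populations
#' @param agent An [Agent].
#' @return A list with `t`, `pos` (1 x d matrix), `vel`, `head`.
#' @export
agent_state <- function(agent) {
  st <- agent$state
  if (agent$env$dimensionality == "1D")
    return(list(t = st$t, pos = matrix(st$position, 1, 1),
                vel = st$velocity, head = st$head_direction))
  list(t = st$t, pos = matrix(st$position, 1, 2), vel = st$velocity,
       head = st$head_direction)
}
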