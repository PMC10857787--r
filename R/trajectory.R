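# Imported trajectories: cubic-spline interpolation and smooth upsampling of
# (possibly low-rate) position recordings, replacing the random motion model.

#' Import a trajectory for spline playback
#'
#' Low temporal-resolution position data are interpolated with cubic splines
#' so they can be replayed at any timestep, turning e.g. 2 Hz tracking data
#' into the high-rate state stream needed to simulate neural activity.
#' During playback the agent is not subject to wall repulsion or collision
#' handling.
#'
#' @param times Strictly increasing sample times (s), length >= 4.
#' @param positions Matrix of positions (n x d) or vector (1D), in metres.
#' @param env An [Arena]; positions must lie inside it.
#' @return An object of class `"ImportedTrajectory"`.
#' @export
import_trajectory <- function(times, positions, env) {
  positions <- .as_points(positions)
  if (length(times) < 4) stop("need at least 4 samples to fit a cubic spline")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (nrow(positions) != length(times))
    stop("`times` and `positions` must have the same length")
  if (!all(is_inside(env, positions)))
    stop("all positions must lie inside the arena")
  interp <- lapply(seq_len(ncol(positions)), function(k)
    stats::splinefun(times, positions[, k], method = "fmm"))
  structure(list(times = times, positions = positions, interp = interp,
                 t_range = range(times), dim = ncol(positions)),
            class = "ImportedTrajectory")
}

#' Evaluate an imported trajectory at arbitrary times
#'
#' Times outside the recorded range are clamped to its endpoints.
#'
#' @param traj An [import_trajectory] result.
#' @param t Vector of query times (s).
#' @return An n x d matrix of positions.
#' @export
trajectory_position <- function(traj, t) {
  t <- pmin(pmax(t, traj$t_range[1]), traj$t_range[2])
  sapply(traj$interp, function(f) f(t)) |> matrix(ncol = traj$dim)
}

#' Replay an imported trajectory at a fixed timestep
#'
#' @param traj An [import_trajectory] result.
#' @param dt Playback timestep (s).
#' @return A data.frame with columns `t`, positions (`x[, y]`), velocities
#'   (`vx[, vy]`, central finite differences of the spline) and head
#'   direction (`hx[, hy]`, the normalised velocity).
#' @export
playback <- function(traj, dt) {
  if (dt <= 0) stop("`dt` must be positive")
  t <- seq(traj$t_range[1], traj$t_range[2], by = dt)
  pos <- trajectory_position(traj, t)
  h <- 1e-4
  vel <- sapply(seq_len(traj$dim), function(k) {
    f <- traj$interp[[k]]
    (f(pmin(t + h, traj$t_range[2])) - f(pmax(t - h, traj$t_range[1]))) /
      (pmin(t + h, traj$t_range[2]) - pmax(t - h, traj$t_range[1]))
  }) |> matrix(ncol = traj$dim)
  if (traj$dim == 2) {
    sp <- sqrt(rowSums(vel^2))
    head <- vel / ifelse(sp > 0, sp, 1)
    data.frame(t = t, x = pos[, 1], y = pos[, 2],
               vx = vel[, 1], vy = vel[, 2], speed = sp,
               hx = head[, 1], hy = head[, 2])
  } else {
    data.frame(t = t, x = pos[, 1], v = vel[, 1],
               h = sign(vel[, 1] + (vel[, 1] == 0)))
  }
}

#' Attach an imported trajectory to an agent
#'
#' Subsequent [update_agent]/[simulate_agent] calls move the agent along the
#' spline instead of the random motion model; wall repulsion and collision
#' handling are disabled.
#'
#' @param agent An [Agent].
#' @param traj An [import_trajectory] result.
#' @return The modified agent, positioned at the trajectory start.
#' @export
set_trajectory <- function(agent, traj) {
  stopifnot(inherits(traj, "ImportedTrajectory"))
  agent$trajectory <- traj
  agent$state$t <- traj$t_range[1]
  p0 <- drop(trajectory_position(traj, traj$t_range[1]))
  agent$state$position <- p0
  agent
}

.update_agent_imported <- function(agent, dt) {
  traj <- agent$trajectory
  st <- agent$state
  t_new <- min(st$t + dt, traj$t_range[2])
  p_new <- drop(trajectory_position(traj, t_new))
  v <- if (t_new > st$t) (p_new - st$position) / (t_new - st$t) else
    st$velocity
  st$t <- t_new
  st$position <- p_new
  st$velocity <- v
  sp <- sqrt(sum(v^2))
  if (agent$env$dimensionality == "2D") {
    if (sp > 0) st$head_direction <- v / sp
    st$theta <- atan2(v[2], v[1]) %% (2 * pi)
  } else if (v != 0) st$head_direction <- sign(v)
  agent$state <- st
  agent
}

.simulate_imported <- function(agent, n, dt) {
  d2 <- agent$env$dimensionality == "2D"
  nc <- if (d2) 9L else 4L
  cn <- if (d2) c("t", "x", "y", "vx", "vy", "speed", "omega", "hx", "hy")
        else c("t", "x", "v", "h")
  H <- matrix(NA_real_, n, nc, dimnames = list(NULL, cn))
  for (i in seq_len(n)) {
    agent <- .update_agent_imported(agent, dt)
    st <- agent$state
    if (d2) {
      H[i, ] <- c(st$t, st$position, st$velocity,
                  sqrt(sum(st$velocity^2)), 0, st$head_direction)
    } else H[i, ] <- c(st$t, st$position, st$velocity, st$head_direction)
  }
  agent$history <- as.data.frame(H)
  agent
}

#' Write / read trajectory CSV (`t,x[,y]` schema)
#'
#' @param history A data.frame with columns `t`, `x` and (2D) `y`; extra
#'   columns such as velocities are preserved on write.
#' @param path File path.
#' @return `read_trajectory_csv` returns a data.frame.
#' @export
write_trajectory_csv <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t", "x") %in% names(df)))
    stop("trajectory CSV must have columns `t,x[,y]`")
  df
}
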