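# Direction-, velocity- and speed-tuned cells, theta phase-precessing place
# cells, and Gaussian-process random spatial receptive fields.

#' Head direction cell population
#'
#' In 2D each cell has a von Mises tuning curve over the head-direction
#' angle, normalised by its peak `exp(kappa)` so the pre-scaled maximum is
#' 1.0; by default tuning means are evenly spaced over 360 degrees and all
#' widths are 3 degrees. In 1D there are always exactly two cells, one for
#' leftward and one for rightward motion (`max(0, sgn(+/- v))`).
#'
#' @param env An [Arena].
#' @param n Number of cells (ignored in 1D, where n = 2).
#' @param tuning_mean Preferred directions (rad); default evenly spaced.
#' @param sigma_angle Angular tuning width (degrees), default 3; the von
#'   Mises concentration is `kappa = 1 / sigma` (radians).
#' @inheritParams PlaceCells
#' @return A population of class `c("HeadDirectionCells", "Neurons")`.
#' @export
HeadDirectionCells <- function(env, n = 10, tuning_mean = NULL,
                               sigma_angle = 3,
                               max_fr = 1, min_fr = 0, noise_std = 0,
                               noise_coherence_time = 0.5,
                               name = "HeadDirectionCells") {
  if (env$dimensionality == "1D") n <- 2L
  if (is.null(tuning_mean)) tuning_mean <- 2 * pi * (seq_len(n) - 1) / n
  pop <- .neurons_base(env, n, name, max_fr, min_fr, noise_std,
                       noise_coherence_time)
  pop$tuning_mean <- rep_len(tuning_mean, n)
  pop$kappa <- 1 / (rep_len(sigma_angle, n) * pi / 180)
  class(pop) <- c("HeadDirectionCells", "Neurons")
  pop
}

#' @export
raw_rates.HeadDirectionCells <- function(pop, state, ...) {
  if (pop$env$dimensionality == "1D") {
    v <- state$vel
    return(matrix(c(max(0, sign(v)), max(0, sign(-v))), 1, 2))
  }
  th <- atan2(state$head[2], state$head[1])
  matrix(exp(pop$kappa * (cos(th - pop$tuning_mean) - 1)),
         nrow(state$pos), pop$n, byrow = TRUE)
}

#' Velocity cell population
#'
#' Like head direction cells but encoding the full velocity vector: in 2D
#' the von Mises direction tuning is multiplied by `speed / sigma_v` where
#' `sigma_v` is the agent's typical speed scale, so pre-scaled rates are
#' O(1). In 1D there are two rectified linear cells
#' `max(0, +/- v / (sigma_v + mu_v))`.
#'
#' @param speed_scale Speed normalisation (m/s): the Rayleigh scale
#'   `sigma_v` in 2D, or `sigma_v + mu_v` in 1D.
#' @inheritParams HeadDirectionCells
#' @return A population of class `c("VelocityCells", "Neurons")`.
#' @export
VelocityCells <- function(env, n = 10, tuning_mean = NULL, sigma_angle = 3,
                          speed_scale = 0.08,
                          max_fr = 1, min_fr = 0, noise_std = 0,
                          noise_coherence_time = 0.5,
                          name = "VelocityCells") {
  pop <- HeadDirectionCells(env, n, tuning_mean, sigma_angle, max_fr,
                            min_fr, noise_std, noise_coherence_time, name)
  pop$speed_scale <- speed_scale
  class(pop) <- c("VelocityCells", class(pop)[-1])
  pop
}

#' @export
raw_rates.VelocityCells <- function(pop, state, ...) {
  if (pop$env$dimensionality == "1D") {
    v <- state$vel / pop$speed_scale
    return(matrix(c(max(0, v), max(0, -v)), 1, 2))
  }
  v <- state$vel
  sp <- sqrt(sum(v^2))
  thv <- atan2(v[2], v[1])
  matrix((sp / pop$speed_scale) *
           exp(pop$kappa * (cos(thv - pop$tuning_mean) - 1)),
         nrow(state$pos), pop$n, byrow = TRUE)
}

#' Single speed cell
#'
#' Encodes the scaled speed `||v|| / sigma_v` (1D: `|v| / (sigma_v + mu_v)`).
#'
#' @inheritParams VelocityCells
#' @return A population of class `c("SpeedCell", "Neurons")` with one cell.
#' @export
SpeedCell <- function(env, speed_scale = 0.08, max_fr = 1, min_fr = 0,
                      noise_std = 0, noise_coherence_time = 0.5,
                      name = "SpeedCell") {
  pop <- .neurons_base(env, 1L, name, max_fr, min_fr, noise_std,
                       noise_coherence_time)
  pop$speed_scale <- speed_scale
  class(pop) <- c("SpeedCell", "Neurons")
  pop
}

#' @export
raw_rates.SpeedCell <- function(pop, state, ...) {
  sp <- sqrt(sum(state$vel^2))
  matrix(sp / pop$speed_scale, nrow(state$pos), 1)
}

# --- Phase precession -----------------------------------------------------

#' Theta phase-precessing place cells
#'
#' Place cells whose spatial rate is multiplied by a theta modulation factor
#' `2*pi*f_VM(phi_theta | phi*_i, kappa_theta)` (a normalised von Mises in
#' the theta phase `phi_theta = 2*pi*nu*t mod 2*pi`, so the factor averages
#' to 1 over a cycle and peaks at `exp(kappa)/I0(kappa) > 1` -- the
#' documented exception to the "pre-scaled max of 1" rule). The preferred
#' phase precesses linearly with the signed distance travelled through the
#' field along the current direction of motion:
#' `phi*_i = pi - beta*pi*d_i/sigma_i` with `d_i = (x - x_i) . v_hat` and
#' field boundary `sigma_i = 2*w_i` for gaussian cells, else `w_i`. A cell's
#' firing therefore peaks at phase `pi + beta*pi` on field entry, `pi` at the
#' centre and `pi - beta*pi` on exit. At zero speed the direction of travel
#' is undefined and the factor is held at 1.
#'
#' @param theta_freq Theta frequency `nu` (Hz), default 10.
#' @param kappa Phase concentration `kappa_theta`, default 1.
#' @param beta Precession fraction `beta` in (0, 1), default 0.5.
#' @inheritParams PlaceCells
#' @return A population of class
#'   `c("PhasePrecessingPlaceCells", "PlaceCells", "Neurons")`.
#' @export
PhasePrecessingPlaceCells <- function(env, n = 10, widths = 0.2,
                                      centres = NULL,
                                      response = c("gaussian",
                                                   "gaussian_threshold",
                                                   "diff_of_gaussians",
                                                   "top_hat", "one_hot"),
                                      wall_geometry = c("geodesic",
                                                        "line_of_sight",
                                                        "euclidean"),
                                      theta_freq = 10, kappa = 1, beta = 0.5,
                                      max_fr = 1, min_fr = 0, noise_std = 0,
                                      noise_coherence_time = 0.5,
                                      name = "PhasePrecessingPlaceCells") {
  if (beta <= 0 || beta >= 1) stop("`beta` must be in (0, 1)")
  pop <- PlaceCells(env, n, widths, centres, match.arg(response),
                    match.arg(wall_geometry), max_fr, min_fr, noise_std,
                    noise_coherence_time, name)
  pop$theta_freq <- theta_freq
  pop$theta_kappa <- kappa
  pop$theta_beta <- beta
  class(pop) <- c("PhasePrecessingPlaceCells", class(pop))
  pop
}

#' Theta modulation factor of phase-precessing place cells
#'
#' @param pop A [PhasePrecessingPlaceCells] population.
#' @param pos m x 2 matrix of positions.
#' @param vel Current velocity (length-2).
#' @param t Current time (s).
#' @return m x n matrix of multiplicative factors.
#' @export
phase_precession_factor <- function(pop, pos, vel, t) {
  m <- nrow(pos)
  sp <- sqrt(sum(vel^2))
  if (sp == 0) return(matrix(1, m, pop$n))
  vhat <- vel / sp
  phase <- (2 * pi * pop$theta_freq * t) %% (2 * pi)
  sigma_i <- if (pop$response == "gaussian") 2 * pop$widths else pop$widths
  FFac <- matrix(1, m, pop$n)
  for (i in seq_len(pop$n)) {
    d_i <- (pos[, 1] - pop$centres[i, 1]) * vhat[1] +
      (pos[, 2] - pop$centres[i, 2]) * vhat[2]
    phi_star <- pi - pop$theta_beta * pi * d_i / sigma_i[i]
    FFac[, i] <- exp(pop$theta_kappa * cos(phase - phi_star)) /
      besselI(pop$theta_kappa, 0)
  }
  FFac
}

#' @export
raw_rates.PhasePrecessingPlaceCells <- function(pop, state, ...) {
  spatial <- raw_rates.PlaceCells(pop, state)
  tt <- if (is.null(state$t)) 0 else state$t
  vel <- if (is.null(state$vel)) c(0, 0) else state$vel
  spatial * phase_precession_factor(pop, state$pos, vel, tt)
}

# --- Random spatial fields ------------------------------------------------

#' Random spatial neurons (Gaussian-process receptive fields)
#'
#' Each cell has a locally smooth but globally random spatial field with an
#' RBF kernel `k(x, x') = exp(-d(x, x')^2 / 2l^2)`, where `d` is the
#' environmental distance (geodesic by default, so fields are smooth
#' everywhere except across walls). At initialisation target values are
#' drawn at a grid of locations at least as dense as the lengthscale from
#' `N(0, K)`; at query time the rate is the kernel-weighted mean of the
#' targets -- a cheap approximation to full GP interpolation. Outputs are
#' unconstrained reals, so min/max scaling is skipped for this class.
#'
#' @param lengthscale Kernel lengthscale `l` (m), default 0.1.
#' @param target_spacing Spacing of the target-location grid (m); default
#'   `lengthscale / 2`.
#' @inheritParams PlaceCells
#' @return A population of class `c("RandomSpatialNeurons", "Neurons")`.
#' @export
RandomSpatialNeurons <- function(env, n = 10, lengthscale = 0.1,
                                 wall_geometry = c("geodesic",
                                                   "line_of_sight",
                                                   "euclidean"),
                                 target_spacing = NULL,
                                 noise_std = 0, noise_coherence_time = 0.5,
                                 name = "RandomSpatialNeurons") {
  wall_geometry <- match.arg(wall_geometry)
  if (lengthscale <= 0) stop("`lengthscale` must be positive")
  if (is.null(target_spacing)) target_spacing <- lengthscale / 2
  if (target_spacing > lengthscale)
    stop("`target_spacing` must not exceed the lengthscale")
  g <- .ratemap_grid(env, target_spacing)
  targets <- g$pos[is_inside(env, g$pos), , drop = FALSE]
  nt <- nrow(targets)
  D <- matrix(0, nt, nt)
  for (j in seq_len(nt))
    D[, j] <- env_distance(env, targets[j, ], targets,
                           geometry = wall_geometry)
  K <- exp(-D^2 / (2 * lengthscale^2))
  K[!is.finite(D)] <- 0
  # geodesic/line-of-sight kernels need not be positive definite, so sample
  # through an eigendecomposition with negative eigenvalues clipped to zero
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  L <- diag(sqrt(pmax(eg$values, 0))) %*% t(eg$vectors)
  targets_F <- matrix(stats::rnorm(n * nt), n, nt) %*% L  # rows ~ N(0, K+)
  pop <- .neurons_base(env, n, name, scale = FALSE)
  pop$noise_std <- noise_std
  pop$noise_coherence_time <- noise_coherence_time
  pop$lengthscale <- lengthscale
  pop$wall_geometry <- wall_geometry
  pop$targets <- targets
  pop$target_values <- targets_F
  class(pop) <- c("RandomSpatialNeurons", "Neurons")
  pop
}

#' @export
raw_rates.RandomSpatialNeurons <- function(pop, state, ...) {
  pos <- state$pos
  nt <- nrow(pop$targets)
  W <- matrix(0, nrow(pos), nt)
  for (j in seq_len(nt)) {
    d <- env_distance(pop$env, pop$targets[j, ], pos,
                      geometry = pop$wall_geometry)
    w <- exp(-d^2 / (2 * pop$lengthscale^2))
    w[!is.finite(d)] <- 0
    W[, j] <- w
  }
  den <- rowSums(W)
  den[den == 0] <- 1
  (W %*% t(pop$target_values)) / den
}
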