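# Vector cells: boundary-, object- and agent-selective populations tuned to
# features at a preferred distance and angle, in allocentric or egocentric
# reference frames, including field-of-view tilings.

# Sample per-cell vector tunings. Angles are stored in radians. kappa is the
# von Mises concentration 1/sigma_phi. The default distance tuning width
# grows linearly with tuning distance: sigma_d = d / beta + xi with
# (xi, beta) = (0.08, 12).
.sample_vector_tunings <- function(n, tuning_distance = c(0, 0.3),
                                   sigma_distance = c(0.08, 12),
                                   tuning_angle = c(0, 360),
                                   sigma_angle = c(10, 30)) {
  d <- if (length(tuning_distance) == n && n != 2) tuning_distance
       else stats::runif(n, tuning_distance[1], tuning_distance[2])
  sd_d <- if (length(sigma_distance) == 2)
    d / sigma_distance[2] + sigma_distance[1]
  else rep_len(sigma_distance, n)
  phi <- if (length(tuning_angle) == n && n != 2) tuning_angle * pi / 180
         else stats::runif(n, tuning_angle[1], tuning_angle[2]) * pi / 180
  sphi <- if (length(sigma_angle) == n && n != 2) sigma_angle * pi / 180
          else stats::runif(n, sigma_angle[1], sigma_angle[2]) * pi / 180
  data.frame(d = d, sigma_d = sd_d, phi = phi, sigma_phi = sphi,
             kappa = 1 / sphi)
}

#' Single-feature vector-cell response
#'
#' The contribution of one feature at distance `d` and angle `phi` (already
#' expressed in the cell's reference frame) is the product of a Gaussian
#' radial tuning and a von Mises angular tuning. The von Mises factor is
#' normalised by its peak `exp(kappa)` so the maximum contribution is exactly
#' 1 (boundary vector cells instead renormalise empirically after
#' integration).
#'
#' @param d Feature distance(s) (m).
#' @param phi Feature angle(s) (rad) in the cell's frame.
#' @param tuning A one-row data.frame with `d`, `sigma_d`, `phi`, `kappa`
#'   (see `tunings` field of vector-cell populations).
#' @return Response value(s) in `[0, 1]`.
#' @export
vector_cell_contribution <- function(d, phi, tuning) {
  exp(-(tuning$d - d)^2 / (2 * tuning$sigma_d^2)) *
    exp(tuning$kappa * (cos(phi - tuning$phi) - 1))
}

.heading_angle <- function(head) atan2(head[2], head[1])

# --- Boundary vector cells ------------------------------------------------

#' Boundary vector cell population
#'
#' Each cell integrates, over the full 360 degree field of view (numeric step
#' `dtheta`), the vector-cell response to the nearest line-of-sight boundary
#' segment along each ray (walls occluded by other walls do not contribute).
#' Rates are multiplied by a per-cell constant `K_i = 1 / max_x F_i(x)`,
#' estimated at initialisation over a grid of spacing `dx_norm`, so the
#' pre-scaled rate-map maximum is 1.0 Hz. Egocentric cells measure ray
#' angles relative to the agent's heading.
#'
#' @param env An [Arena] (2D) with at least one wall in play (i.e. solid
#'   boundaries and/or interior walls).
#' @param n Number of cells.
#' @param reference_frame `"allocentric"` (default) or `"egocentric"`.
#' @param tuning_distance,sigma_distance,tuning_angle,sigma_angle Tuning
#'   parameters (ranges to sample from, or length-n vectors). Angles in
#'   degrees; `sigma_distance = c(xi, beta)` gives the linear rule
#'   `sigma_d = d / beta + xi`.
#' @param tunings Optional pre-built tuning data.frame (overrides the
#'   sampling arguments); see [build_field_of_view].
#' @param dtheta Angular integration step (degrees), default 2.
#' @param dx_norm Grid spacing (m) for the empirical normalisation,
#'   defaulting to the arena `dx`.
#' @inheritParams PlaceCells
#' @return A population of class `c("BoundaryVectorCells", "VectorCells",
#'   "Neurons")`.
#' @export
BoundaryVectorCells <- function(env, n = 10,
                                reference_frame = c("allocentric",
                                                    "egocentric"),
                                tuning_distance = c(0, 0.3),
                                sigma_distance = c(0.08, 12),
                                tuning_angle = c(0, 360),
                                sigma_angle = c(10, 30),
                                tunings = NULL, dtheta = 2, dx_norm = NULL,
                                max_fr = 1, min_fr = 0, noise_std = 0,
                                noise_coherence_time = 0.5,
                                name = "BoundaryVectorCells") {
  stopifnot(env$dimensionality == "2D")
  if (dtheta <= 0 || dtheta >= 360) stop("`dtheta` must be in (0, 360)")
  reference_frame <- match.arg(reference_frame)
  if (is.null(tunings))
    tunings <- .sample_vector_tunings(n, tuning_distance, sigma_distance,
                                      tuning_angle, sigma_angle)
  n <- nrow(tunings)
  pop <- .neurons_base(env, n, name, max_fr, min_fr, noise_std,
                       noise_coherence_time)
  pop$tunings <- tunings
  pop$reference_frame <- reference_frame
  pop$dtheta <- dtheta
  pop$K <- rep(1, n)
  class(pop) <- c("BoundaryVectorCells", "VectorCells", "Neurons")
  # empirical normalisation over the dx grid (reference heading +x)
  if (is.null(dx_norm)) dx_norm <- env$dx
  g <- .ratemap_grid(env, dx_norm)
  inside <- is_inside(env, g$pos)
  Fm <- .bvc_unnormalised(pop, g$pos[inside, , drop = FALSE], c(1, 0))
  mx <- apply(Fm, 2, max)
  pop$K <- ifelse(mx > 0, 1 / mx, 1)
  pop
}

# Unnormalised BVC rates at positions (m x 2) for a single heading.
.bvc_unnormalised <- function(pop, pos, head) {
  env <- pop$env
  walls <- .collision_walls(env)
  dth <- pop$dtheta * pi / 180
  dirs <- seq(0, 2 * pi - dth / 2, by = dth)
  offset <- if (pop$reference_frame == "egocentric") .heading_angle(head) else 0
  m <- nrow(pos)
  Rhit <- matrix(Inf, m, length(dirs))
  for (k in seq_along(dirs))
    Rhit[, k] <- .ray_first_hit(pos, dirs[k] + offset, walls)
  FF <- matrix(0, m, pop$n)
  for (i in seq_len(pop$n)) {
    tun <- pop$tunings[i, ]
    radial <- exp(-(tun$d - Rhit)^2 / (2 * tun$sigma_d^2))
    radial[!is.finite(Rhit)] <- 0
    vm <- exp(tun$kappa * (cos(dirs - tun$phi) - 1))
    FF[, i] <- radial %*% (vm * dth)
  }
  FF
}

#' @export
raw_rates.BoundaryVectorCells <- function(pop, state, ...) {
  head <- if (is.null(state$head)) c(1, 0) else state$head
  FF <- .bvc_unnormalised(pop, state$pos, head)
  sweep(FF, 2, pop$K, "*")
}

# --- Object vector cells --------------------------------------------------

#' Object vector cell population
#'
#' Each cell is tuned to objects of one type at a preferred distance and
#' angle; its rate is the sum of the contributions of all matching objects
#' (so two coincident objects can drive the rate to 2). With
#' `walls_occlude = TRUE` (default) objects hidden behind a wall contribute
#' nothing.
#'
#' @param env An [Arena] (2D) containing objects (see [add_object]).
#' @param object_tuning_type `"random"` (each cell picks a random type
#'   present in the arena) or an integer (vector) of type labels.
#' @param walls_occlude Whether walls hide objects behind them.
#' @inheritParams BoundaryVectorCells
#' @return A population of class `c("ObjectVectorCells", "VectorCells",
#'   "Neurons")`.
#' @export
ObjectVectorCells <- function(env, n = 10,
                              reference_frame = c("allocentric",
                                                  "egocentric"),
                              object_tuning_type = "random",
                              walls_occlude = TRUE,
                              tuning_distance = c(0, 0.3),
                              sigma_distance = c(0.08, 12),
                              tuning_angle = c(0, 360),
                              sigma_angle = c(10, 30),
                              tunings = NULL,
                              max_fr = 1, min_fr = 0, noise_std = 0,
                              noise_coherence_time = 0.5,
                              name = "ObjectVectorCells") {
  stopifnot(env$dimensionality == "2D")
  reference_frame <- match.arg(reference_frame)
  if (is.null(tunings))
    tunings <- .sample_vector_tunings(n, tuning_distance, sigma_distance,
                                      tuning_angle, sigma_angle)
  n <- nrow(tunings)
  types_present <- unique(env$objects$type)
  tuning_type <- if (identical(object_tuning_type, "random")) {
    if (length(types_present) == 0) rep(1L, n)
    else sample(types_present, n, replace = TRUE)
  } else rep_len(as.integer(object_tuning_type), n)
  pop <- .neurons_base(env, n, name, max_fr, min_fr, noise_std,
                       noise_coherence_time)
  pop$tunings <- tunings
  pop$tuning_type <- tuning_type
  pop$reference_frame <- reference_frame
  pop$walls_occlude <- walls_occlude
  class(pop) <- c("ObjectVectorCells", "VectorCells", "Neurons")
  pop
}

# Sum of vector-cell contributions of point features (m x 2 positions of the
# agent against a fixed feature location), shared by OVCs and AVCs.
.point_feature_rates <- function(pop, pos, head, feature, cells) {
  env <- pop$env
  m <- nrow(pos)
  dxv <- feature[1] - pos[, 1]
  dyv <- feature[2] - pos[, 2]
  if (env$boundary_conditions == "periodic") {
    ext <- env_extent(env)
    dxv <- .wrap_disp(dxv, ext[1]); dyv <- .wrap_disp(dyv, ext[2])
  }
  d <- sqrt(dxv^2 + dyv^2)
  ang <- atan2(dyv, dxv)
  if (pop$reference_frame == "egocentric")
    ang <- ang - .heading_angle(head)
  vis <- rep(TRUE, m)
  if (isTRUE(pop$walls_occlude) && nrow(.interior_walls(env)) > 0)
    vis <- .los_mask(feature, pos, .interior_walls(env))
  FF <- matrix(0, m, pop$n)
  for (i in cells) {
    tun <- pop$tunings[i, ]
    g <- vector_cell_contribution(d, ang, tun)
    g[!vis] <- 0
    FF[, i] <- g
  }
  FF
}

#' @export
raw_rates.ObjectVectorCells <- function(pop, state, ...) {
  pos <- state$pos
  head <- if (is.null(state$head)) c(1, 0) else state$head
  FF <- matrix(0, nrow(pos), pop$n)
  objs <- pop$env$objects
  for (j in seq_len(nrow(objs))) {
    cells <- which(pop$tuning_type == objs$type[j])
    if (!length(cells)) next
    FF <- FF + .point_feature_rates(pop, pos, head,
                                    c(objs$x[j], objs$y[j]), cells)
  }
  FF
}

# --- Agent vector cells ---------------------------------------------------

#' Agent vector cell population
#'
#' Like object vector cells but selective to the position of one other agent,
#' passed per update as `other_pos` (or fixed via the `other_position`
#' field, used e.g. for rate maps).
#'
#' @param other_position Default position of the observed agent (length-2).
#' @inheritParams ObjectVectorCells
#' @return A population of class `c("AgentVectorCells", "VectorCells",
#'   "Neurons")`.
#' @export
AgentVectorCells <- function(env, n = 10,
                             reference_frame = c("allocentric",
                                                 "egocentric"),
                             walls_occlude = TRUE,
                             other_position = NULL,
                             tuning_distance = c(0, 0.3),
                             sigma_distance = c(0.08, 12),
                             tuning_angle = c(0, 360),
                             sigma_angle = c(10, 30),
                             tunings = NULL,
                             max_fr = 1, min_fr = 0, noise_std = 0,
                             noise_coherence_time = 0.5,
                             name = "AgentVectorCells") {
  stopifnot(env$dimensionality == "2D")
  reference_frame <- match.arg(reference_frame)
  if (is.null(tunings))
    tunings <- .sample_vector_tunings(n, tuning_distance, sigma_distance,
                                      tuning_angle, sigma_angle)
  n <- nrow(tunings)
  pop <- .neurons_base(env, n, name, max_fr, min_fr, noise_std,
                       noise_coherence_time)
  pop$tunings <- tunings
  pop$reference_frame <- reference_frame
  pop$walls_occlude <- walls_occlude
  pop$other_position <- other_position
  class(pop) <- c("AgentVectorCells", "VectorCells", "Neurons")
  pop
}

#' @export
raw_rates.AgentVectorCells <- function(pop, state, ..., other_pos = NULL) {
  if (is.null(other_pos)) other_pos <- pop$other_position
  if (is.null(other_pos)) stop("AgentVectorCells need `other_pos`")
  head <- if (is.null(state$head)) c(1, 0) else state$head
  .point_feature_rates(pop, state$pos, head, other_pos, seq_len(pop$n))
}

# --- Field-of-view arrangements -------------------------------------------

#' Tile a field of view with egocentric vector-cell tunings
#'
#' Builds concentric rows of egocentric cells covering distances
#' `distance_range` and angles `angle_range` (degrees from the forward
#' heading, mirrored left and right). Receptive fields are approximately
#' circular: `sigma_d = d * sigma_phi = delta(d)`, where for the
#' `"diverging"` manifold `delta(d) = xi0 + d / beta` grows with distance
#' (`xi0 = spatial_resolution - r_min / beta`) and for `"uniform"` it is
#' constant. Row radii advance by the local `delta`; angular spacing within
#' a row keeps the arc length near `delta`.
#'
#' @param distance_range `c(r_min, r_max)` (m).
#' @param angle_range `c(theta_min, theta_max)` in degrees from straight
#'   ahead.
#' @param spatial_resolution Resolution `delta0` (m) of the innermost row.
#' @param manifold `"diverging"` (default) or `"uniform"`.
#' @param beta Inverse gradient of the receptive-field growth (diverging
#'   manifold only).
#' @return A tuning data.frame (columns `d`, `sigma_d`, `phi`, `sigma_phi`,
#'   `kappa`) suitable for the `tunings` argument of vector-cell
#'   constructors.
#' @export
build_field_of_view <- function(distance_range = c(0.02, 0.4),
                                angle_range = c(0, 75),
                                spatial_resolution = 0.02,
                                manifold = c("diverging", "uniform"),
                                beta = 5) {
  manifold <- match.arg(manifold)
  r_min <- distance_range[1]; r_max <- distance_range[2]
  if (r_min >= r_max) stop("distance_range must satisfy r_min < r_max")
  if (spatial_resolution <= 0) stop("`spatial_resolution` must be positive")
  if (spatial_resolution >= r_max - r_min)
    stop("`spatial_resolution` too coarse for the distance range")
  xi0 <- spatial_resolution - r_min / beta
  delta <- function(d) if (manifold == "diverging") xi0 + d / beta
                       else rep(spatial_resolution, length(d))
  th_min <- angle_range[1] * pi / 180; th_max <- angle_range[2] * pi / 180
  rows <- list()
  r <- r_min
  while (r <= r_max + 1e-12) {
    dl <- delta(r)
    dphi <- dl / r
    phi_right <- seq(th_min, th_max, by = dphi)
    phis <- sort(unique(c(-rev(phi_right), phi_right)))
    rows[[length(rows) + 1]] <-
      data.frame(d = r, sigma_d = dl, phi = phis, sigma_phi = dl / r,
                 kappa = r / dl)
    r <- r + dl
  }
  do.call(rbind, rows)
}

#' Field-of-view boundary vector cells
#'
#' Egocentric [BoundaryVectorCells] with tunings from
#' [build_field_of_view], tiling the agent's field of view. The empirical
#' normalisation grid defaults to a coarser spacing (0.04 m) than plain
#' BVCs because these populations are large.
#'
#' @inheritParams build_field_of_view
#' @inheritParams BoundaryVectorCells
#' @export
FieldOfViewBVCs <- function(env, distance_range = c(0.02, 0.4),
                            angle_range = c(0, 75),
                            spatial_resolution = 0.02,
                            manifold = c("diverging", "uniform"), beta = 5,
                            dtheta = 2, dx_norm = 0.04, ...) {
  tun <- build_field_of_view(distance_range, angle_range,
                             spatial_resolution, manifold, beta)
  BoundaryVectorCells(env, reference_frame = "egocentric", tunings = tun,
                      dtheta = dtheta, dx_norm = dx_norm,
                      name = "FieldOfViewBVCs", ...)
}

#' Field-of-view object vector cells
#' @inheritParams FieldOfViewBVCs
#' @inheritParams ObjectVectorCells
#' @export
FieldOfViewOVCs <- function(env, distance_range = c(0.02, 0.4),
                            angle_range = c(0, 75),
                            spatial_resolution = 0.02,
                            manifold = c("diverging", "uniform"), beta = 5,
                            object_tuning_type = "random", ...) {
  tun <- build_field_of_view(distance_range, angle_range,
                             spatial_resolution, manifold, beta)
  ObjectVectorCells(env, reference_frame = "egocentric", tunings = tun,
                    object_tuning_type = object_tuning_type,
                    name = "FieldOfViewOVCs", ...)
}

#' Field-of-view agent vector cells
#' @inheritParams FieldOfViewBVCs
#' @inheritParams AgentVectorCells
#' @export
FieldOfViewAVCs <- function(env, distance_range = c(0.02, 0.4),
                            angle_range = c(0, 75),
                            spatial_resolution = 0.02,
                            manifold = c("diverging", "uniform"), beta = 5,
                            other_position = NULL, ...) {
  tun <- build_field_of_view(distance_range, angle_range,
                             spatial_resolution, manifold, beta)
  AgentVectorCells(env, reference_frame = "egocentric", tunings = tun,
                   other_position = other_position,
                   name = "FieldOfViewAVCs", ...)
}
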