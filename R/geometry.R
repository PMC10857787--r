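# Environment geometry: continuous 1D/2D arenas with walls, holes and objects.
# All positions are in metres, origin at the lower-left corner, x rightward,
# y upward; angles in radians anticlockwise from +x.

#' Construct a continuous arena
#'
#' An `Arena` is a continuous 1D or 2D domain in which agents move and with
#' respect to which spatially tuned neurons fire. 2D arenas are rectangles of
#' height `scale` and width `scale * aspect` that may contain interior walls
#' (1D segments through which locomotion is not allowed), polygonal holes
#' (treated as outside the arena; their edges become walls) and point objects
#' acting as visual cues. Boundary conditions are `"solid"` (the perimeter
#' behaves as four walls) or `"periodic"` (positions and distances wrap).
#'
#' @param dimensionality `"2D"` (default) or `"1D"`.
#' @param boundary_conditions `"solid"` (default) or `"periodic"`.
#' @param scale Height of the arena (2D) or its length (1D), in metres.
#' @param aspect Aspect ratio; 2D width is `scale * aspect`.
#' @param dx Discretisation length (m) used for rate maps and empirical
#'   normalisation grids.
#' @param walls Interior walls: a list of 2x2 matrices (`rbind(p1, p2)`) or an
#'   n x 4 matrix with columns `x1, y1, x2, y2`.
#' @param holes A list of polygons (each an m x 2 matrix, m >= 3) carved out
#'   of the arena.
#' @param objects An n x 2 matrix of object positions, or a data.frame with
#'   columns `x`, `y` and optionally `type` (integer labels).
#' @return An object of class `"Arena"`.
#' @examples
#' env <- Arena()                       # unit box
#' env <- add_wall(env, rbind(c(0.5, 0), c(0.5, 0.6)))
#' env_distance(env, c(0.25, 0.3), c(0.75, 0.3), geometry = "geodesic")
#' @export
Arena <- function(dimensionality = c("2D", "1D"),
                  boundary_conditions = c("solid", "periodic"),
                  scale = 1.0, aspect = 1.0, dx = 0.01,
                  walls = NULL, holes = NULL, objects = NULL) {
  dimensionality <- match.arg(dimensionality)
  boundary_conditions <- match.arg(boundary_conditions)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("`scale` must be a positive number")
  if (!is.numeric(aspect) || length(aspect) != 1L || aspect <= 0)
    stop("`aspect` must be a positive number")
  if (dx <= 0) stop("`dx` must be positive")

  env <- structure(list(
    dimensionality = dimensionality,
    boundary_conditions = boundary_conditions,
    scale = scale, aspect = aspect, dx = dx,
    walls = matrix(numeric(0), 0, 4,
                   dimnames = list(NULL, c("x1", "y1", "x2", "y2"))),
    holes = list(),
    objects = data.frame(x = numeric(0), y = numeric(0), type = integer(0))
  ), class = "Arena")

  if (!is.null(walls)) {
    for (w in .as_wall_list(walls)) env <- add_wall(env, w)
  }
  if (!is.null(holes)) {
    for (h in holes) env <- add_hole(env, h)
  }
  if (!is.null(objects)) {
    objects <- .as_object_df(objects)
    for (i in seq_len(nrow(objects)))
      env <- add_object(env, c(objects$x[i], objects$y[i]), objects$type[i])
  }
  env
}

#' @export
print.Arena <- function(x, ...) {
  ext <- env_extent(x)
  cat(sprintf("<Arena %s, %s boundaries, extent %s m>\n", x$dimensionality,
              x$boundary_conditions, paste(signif(ext, 4), collapse = " x ")))
  cat(sprintf("  %d interior wall(s), %d hole(s), %d object(s)\n",
              nrow(x$walls) - .n_hole_walls(x), length(x$holes),
              nrow(x$objects)))
  invisible(x)
}

.n_hole_walls <- function(env) sum(vapply(env$holes, nrow, 1L))

.as_wall_list <- function(walls) {
  if (is.matrix(walls) && ncol(walls) == 4)
    return(lapply(seq_len(nrow(walls)),
                  function(i) rbind(walls[i, 1:2], walls[i, 3:4])))
  if (is.matrix(walls) && all(dim(walls) == c(2, 2))) return(list(walls))
  if (is.list(walls)) return(lapply(walls, function(w) {
    w <- as.matrix(w)
    if (!all(dim(w) == c(2, 2))) stop("each wall must be a 2x2 matrix")
    w
  }))
  stop("`walls` must be a list of 2x2 matrices or an n x 4 matrix")
}

.as_object_df <- function(objects) {
  if (is.data.frame(objects)) {
    if (is.null(objects$type)) objects$type <- 1L
    return(objects[, c("x", "y", "type")])
  }
  objects <- as.matrix(objects)
  data.frame(x = objects[, 1], y = objects[, 2], type = 1L)
}

#' Arena extent
#'
#' @param env An [Arena].
#' @return For 2D, `c(width, height)`; for 1D, the length.
#' @export
env_extent <- function(env) {
  if (env$dimensionality == "1D") return(env$scale)
  c(env$scale * env$aspect, env$scale)
}

# Perimeter edges as a wall matrix (anticlockwise from origin).
.perimeter_walls <- function(env) {
  ext <- env_extent(env)
  W <- ext[1]; H <- ext[2]
  matrix(c(0, 0, W, 0,
           W, 0, W, H,
           W, H, 0, H,
           0, H, 0, 0), ncol = 4, byrow = TRUE,
         dimnames = list(NULL, c("x1", "y1", "x2", "y2")))
}

# All walls relevant for collisions / repulsion / ray casting.
# Perimeter edges count as walls only under solid boundaries.
.collision_walls <- function(env) {
  if (env$boundary_conditions == "solid")
    rbind(env$walls, .perimeter_walls(env))
  else env$walls
}

#' Add an interior wall
#'
#' @param env An [Arena].
#' @param wall A 2x2 matrix `rbind(p1, p2)` of the wall endpoints (m).
#' @return The modified arena.
#' @export
add_wall <- function(env, wall) {
  wall <- as.matrix(wall)
  if (!all(dim(wall) == c(2, 2))) stop("`wall` must be a 2x2 matrix")
  if (sum((wall[1, ] - wall[2, ])^2) == 0)
    stop("wall endpoints must be distinct")
  env$walls <- rbind(env$walls, c(wall[1, 1], wall[1, 2], wall[2, 1], wall[2, 2]))
  env
}

#' Add a polygonal hole
#'
#' Holes are closed polygons carved out of the arena: their interior counts as
#' outside the environment and their edges behave as walls.
#'
#' @param env An [Arena].
#' @param polygon An m x 2 matrix (m >= 3) of vertices.
#' @return The modified arena.
#' @export
add_hole <- function(env, polygon) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3 || ncol(polygon) != 2)
    stop("a hole needs at least 3 vertices (m x 2 matrix)")
  ext <- env_extent(env)
  if (any(polygon[, 1] < 0 | polygon[, 1] > ext[1] |
          polygon[, 2] < 0 | polygon[, 2] > ext[2]))
    stop("hole vertices must lie inside the arena")
  env$holes <- c(env$holes, list(polygon))
  m <- nrow(polygon)
  edges <- cbind(polygon, polygon[c(2:m, 1), , drop = FALSE])
  colnames(edges) <- c("x1", "y1", "x2", "y2")
  env$walls <- rbind(env$walls, edges)
  env
}

#' Add a point object (visual cue)
#'
#' @param env An [Arena].
#' @param position Length-2 position (m).
#' @param type Integer type label; object vector cells are selective to one
#'   type.
#' @return The modified arena.
#' @export
add_object <- function(env, position, type = 1L) {
  if (!all(is_inside(env, matrix(position, 1))))
    stop("object position must lie inside the arena")
  env$objects <- rbind(env$objects,
                       data.frame(x = position[1], y = position[2],
                                  type = as.integer(type)))
  env
}

.as_points <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = length(p)) else as.matrix(p)
}

# Even-odd point-in-polygon, vectorised over points.
.in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Test whether points lie inside the arena
#'
#' Points inside a hole count as outside.
#'
#' @param env An [Arena].
#' @param p A point or m x d matrix of points.
#' @param tol Numerical slack on the boundary.
#' @return Logical vector.
#' @export
is_inside <- function(env, p, tol = 1e-9) {
  p <- .as_points(p)
  if (env$dimensionality == "1D")
    return(p[, 1] >= -tol & p[, 1] <= env$scale + tol)
  ext <- env_extent(env)
  ok <- p[, 1] >= -tol & p[, 1] <= ext[1] + tol &
    p[, 2] >= -tol & p[, 2] <= ext[2] + tol
  for (h in env$holes) ok <- ok & !.in_polygon(p, h)
  ok
}

#' Wrap positions under periodic boundaries
#'
#' Componentwise modulo into the arena extent; a no-op for solid boundaries.
#'
#' @param env An [Arena].
#' @param p A point or m x d matrix.
#' @return Points of the same shape as `p`.
#' @export
wrap_position <- function(env, p) {
  if (env$boundary_conditions != "periodic") return(p)
  ext <- env_extent(env)
  was_vec <- is.null(dim(p))
  p <- .as_points(p)
  for (k in seq_along(ext)) p[, k] <- p[, k] %% ext[k]
  if (was_vec) drop(p) else p
}

# Minimal-image displacement under periodic boundaries.
.wrap_disp <- function(d, extent) d - extent * round(d / extent)

# --- segment intersection primitives -------------------------------------

# First wall crossed by segment p -> q. Returns list(wall=idx, t, point) or
# NULL. `t_min` excludes the segment start (so an agent sitting on a wall is
# not permanently "colliding").
.first_crossing <- function(p, q, walls, t_min = 1e-12) {
  if (nrow(walls) == 0) return(NULL)
  rx <- q[1] - p[1]; ry <- q[2] - p[2]
  sx <- walls[, 3] - walls[, 1]; sy <- walls[, 4] - walls[, 2]
  qx <- walls[, 1] - p[1]; qy <- walls[, 2] - p[2]
  denom <- rx * sy - ry * sx
  tt <- (qx * sy - qy * sx) / denom
  uu <- (qx * ry - qy * rx) / denom
  ok <- is.finite(tt) & tt >= t_min & tt <= 1 & uu >= 0 & uu <= 1
  if (!any(ok)) return(NULL)
  idx <- which(ok)[which.min(tt[ok])]
  list(wall = idx, t = tt[idx],
       point = c(p[1] + tt[idx] * rx, p[2] + tt[idx] * ry))
}

# Line-of-sight from a single point `a` to rows of `B`, given blocking walls.
# Crossings strictly interior to both segments block; grazing an endpoint
# does not (so geodesic paths may turn exactly at wall tips).
.los_mask <- function(a, B, walls, eps = 1e-10) {
  m <- nrow(B)
  if (nrow(walls) == 0) return(rep(TRUE, m))
  vis <- rep(TRUE, m)
  rx <- B[, 1] - a[1]; ry <- B[, 2] - a[2]
  for (j in seq_len(nrow(walls))) {
    sx <- walls[j, 3] - walls[j, 1]; sy <- walls[j, 4] - walls[j, 2]
    qx <- walls[j, 1] - a[1]; qy <- walls[j, 2] - a[2]
    denom <- rx * sy - ry * sx
    tt <- (qx * sy - qy * sx) / denom
    uu <- (qx * ry - qy * rx) / denom
    blocked <- is.finite(tt) & tt > eps & tt < 1 - eps & uu > eps & uu < 1 - eps
    vis <- vis & !blocked
  }
  vis
}

# Perpendicular (point-to-segment) distance and outward normal for every wall.
# Normal points from the wall toward `p`; for a point exactly on a wall the
# normal is the wall perpendicular with non-negative dot product against the
# fixed reference axis (0.6, 0.8) -- arbitrary but deterministic.
.wall_geometry_at <- function(p, walls) {
  if (nrow(walls) == 0)
    return(list(dist = numeric(0), normal = matrix(numeric(0), 0, 2),
                u = numeric(0)))
  sx <- walls[, 3] - walls[, 1]; sy <- walls[, 4] - walls[, 2]
  len2 <- sx^2 + sy^2
  u <- ((p[1] - walls[, 1]) * sx + (p[2] - walls[, 2]) * sy) / len2
  u <- pmin(pmax(u, 0), 1)
  px <- walls[, 1] + u * sx; py <- walls[, 2] + u * sy
  dxv <- p[1] - px; dyv <- p[2] - py
  d <- sqrt(dxv^2 + dyv^2)
  nx <- ifelse(d > 0, dxv / d, 0)
  ny <- ifelse(d > 0, dyv / d, 0)
  on_wall <- d == 0
  if (any(on_wall)) {
    # fall back to the wall perpendicular, oriented by a fixed axis
    ln <- sqrt(len2[on_wall])
    cx <- -sy[on_wall] / ln; cy <- sx[on_wall] / ln
    flip <- (cx * 0.6 + cy * 0.8) < 0
    nx[on_wall] <- ifelse(flip, -cx, cx)
    ny[on_wall] <- ifelse(flip, -cy, cy)
  }
  list(dist = d, normal = cbind(nx, ny), u = u)
}

#' Perpendicular distances and normals to every wall
#'
#' One entry per wall segment; perimeter edges are included when boundaries
#' are solid. The normal is the unit vector pointing from the wall toward `p`.
#'
#' @param env An [Arena] (2D).
#' @param p A length-2 position inside the arena.
#' @return A data.frame with columns `wall`, `dist`, `nx`, `ny`.
#' @export
vectors_to_walls <- function(env, p) {
  stopifnot(env$dimensionality == "2D")
  walls <- .collision_walls(env)
  g <- .wall_geometry_at(p, walls)
  data.frame(wall = seq_len(nrow(walls)), dist = g$dist,
             nx = g$normal[, 1], ny = g$normal[, 2])
}

#' Detect the first wall crossed by a motion step
#'
#' @param env An [Arena] (2D).
#' @param p_old,p_new Segment endpoints of the attempted step.
#' @return `NULL` if no wall is crossed, else a list with `wall` (index into
#'   the collision wall set), `t` (fraction along the step) and `point`.
#' @export
check_collision <- function(env, p_old, p_new) {
  stopifnot(env$dimensionality == "2D")
  .first_crossing(p_old, p_new, .collision_walls(env))
}

# --- distances ------------------------------------------------------------

# Interior walls = user walls + hole edges (blocking for LOS / geodesic).
.interior_walls <- function(env) env$walls

#' Distance between points under a choice of geometry
#'
#' Three geometries are supported. `"euclidean"` ignores walls.
#' `"line_of_sight"` equals the euclidean distance when no wall obstructs the
#' straight segment and `Inf` otherwise. `"geodesic"` is the length of the
#' shortest wall-avoiding path, computed exactly on a visibility graph over
#' wall endpoints. Under periodic boundaries all three use the minimal wrapped
#' displacement (walls are tiled into neighbouring images for the
#' wall-respecting geometries).
#'
#' @param env An [Arena].
#' @param from A single point (length-d vector).
#' @param to A point or m x d matrix of points.
#' @param geometry One of `"euclidean"`, `"geodesic"`, `"line_of_sight"`.
#' @return Numeric vector of distances (m), possibly `Inf` for
#'   `"line_of_sight"`.
#' @export
env_distance <- function(env, from, to,
                         geometry = c("euclidean", "geodesic", "line_of_sight")) {
  geometry <- match.arg(geometry)
  to <- .as_points(to)
  if (env$dimensionality == "1D") {
    d <- abs(to[, 1] - from[1])
    if (env$boundary_conditions == "periodic")
      d <- abs(.wrap_disp(to[, 1] - from[1], env$scale))
    return(d)
  }
  if (!all(is_inside(env, matrix(from, 1))) || !all(is_inside(env, to)))
    stop("points must lie inside the arena")
  periodic <- env$boundary_conditions == "periodic"
  walls <- .interior_walls(env)

  if (geometry == "euclidean" || nrow(walls) == 0) {
    dxy <- cbind(to[, 1] - from[1], to[, 2] - from[2])
    if (periodic) {
      ext <- env_extent(env)
      dxy[, 1] <- .wrap_disp(dxy[, 1], ext[1])
      dxy[, 2] <- .wrap_disp(dxy[, 2], ext[2])
    }
    return(sqrt(rowSums(dxy^2)))
  }

  if (periodic) return(.periodic_wall_distance(env, from, to, geometry))

  if (geometry == "line_of_sight") {
    d <- sqrt((to[, 1] - from[1])^2 + (to[, 2] - from[2])^2)
    d[!.los_mask(from, to, walls)] <- Inf
    return(d)
  }
  .geodesic_distance(from, to, walls)
}

# Exact geodesic via visibility graph over wall endpoints + Dijkstra.
.geodesic_distance <- function(from, to, walls) {
  nodes <- unique(rbind(walls[, 1:2, drop = FALSE], walls[, 3:4, drop = FALSE]))
  V <- rbind(matrix(from, 1), nodes)
  nv <- nrow(V)
  # pairwise visibility-weighted adjacency
  A <- matrix(Inf, nv, nv)
  for (i in seq_len(nv - 1)) {
    rest <- (i + 1):nv
    vis <- .los_mask(V[i, ], V[rest, , drop = FALSE], walls)
    w <- sqrt((V[rest, 1] - V[i, 1])^2 + (V[rest, 2] - V[i, 2])^2)
    w[!vis] <- Inf
    A[i, rest] <- w
    A[rest, i] <- w
  }
  diag(A) <- 0
  dist <- .dijkstra(A, 1)
  out <- numeric(nrow(to))
  for (b in seq_len(nrow(to))) {
    p <- to[b, ]
    vis <- .los_mask(p, V, walls)
    w <- sqrt((V[, 1] - p[1])^2 + (V[, 2] - p[2])^2)
    cand <- dist[vis] + w[vis]
    out[b] <- if (length(cand)) min(cand) else Inf
  }
  out
}

# Plain O(V^2) Dijkstra; the visibility graphs are tiny.
.dijkstra <- function(A, source) {
  nv <- nrow(A)
  dist <- rep(Inf, nv)
  dist[source] <- 0
  done <- rep(FALSE, nv)
  for (iter in seq_len(nv)) {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    i <- cand[which.min(dist[cand])]
    done[i] <- TRUE
    relax <- dist[i] + A[i, ]
    upd <- relax < dist
    dist[upd] <- relax[upd]
  }
  dist
}

# Wall-respecting distances under periodic boundaries: tile interior walls
# into the 3x3 neighbouring images and take the minimum over target images.
.periodic_wall_distance <- function(env, from, to, geometry) {
  ext <- env_extent(env)
  walls <- .interior_walls(env)
  shifts <- expand.grid(ix = -1:1, iy = -1:1)
  tiled <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(k) {
    s <- c(shifts$ix[k] * ext[1], shifts$iy[k] * ext[2])
    cbind(walls[, 1] + s[1], walls[, 2] + s[2],
          walls[, 3] + s[1], walls[, 4] + s[2])
  }))
  best <- rep(Inf, nrow(to))
  for (k in seq_len(nrow(shifts))) {
    to_k <- cbind(to[, 1] + shifts$ix[k] * ext[1],
                  to[, 2] + shifts$iy[k] * ext[2])
    d <- if (geometry == "line_of_sight") {
      dd <- sqrt((to_k[, 1] - from[1])^2 + (to_k[, 2] - from[2])^2)
      dd[!.los_mask(from, to_k, tiled)] <- Inf
      dd
    } else {
      .geodesic_distance(from, to_k, tiled)
    }
    best <- pmin(best, d)
  }
  best
}

# --- ray casting (boundary vector cells) ----------------------------------

# First-hit distance from each origin along direction `theta`, against all
# collision walls. Returns Inf where no wall is hit (possible only under
# periodic boundaries with no interior walls in range).
.ray_first_hit <- function(origins, theta, walls) {
  m <- nrow(origins)
  if (nrow(walls) == 0) return(rep(Inf, m))
  dx <- cos(theta); dy <- sin(theta)
  best <- rep(Inf, m)
  for (j in seq_len(nrow(walls))) {
    sx <- walls[j, 3] - walls[j, 1]; sy <- walls[j, 4] - walls[j, 2]
    denom <- dx * sy - dy * sx
    if (abs(denom) < 1e-14) next
    qx <- walls[j, 1] - origins[, 1]; qy <- walls[j, 2] - origins[, 2]
    r <- (qx * sy - qy * sx) / denom
    u <- (qx * dy - qy * dx) / denom
    ok <- r > 1e-9 & u >= 0 & u <= 1
    best[ok] <- pmin(best[ok], r[ok])
  }
  best
}
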