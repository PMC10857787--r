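state_at <- function(pos, head = c(1, 0), vel = NULL, t = 0) {
  if (is.null(vel)) vel <- 0.08 * head
  list(t = t, pos = matrix(pos, ncol = 2), vel = vel, head = head)
}

test_that("place cell response functions match their closed forms", {
  env <- Arena()
  w <- 0.2
  ctr <- matrix(c(0.5, 0.5), 1)
  at <- function(resp, d) {
    pc <- PlaceCells(env, n = 1, widths = w, centres = ctr, response = resp,
                     wall_geometry = "euclidean")
    drop(raw_rates(pc, state_at(c(0.5 + d, 0.5))))
  }
  expect_equal(at("gaussian", 0), 1)
  expect_equal(at("gaussian", w), exp(-0.5), tolerance = 1e-12)
  # gaussian_threshold is cropped and levelled exactly at one sd
  expect_equal(at("gaussian_threshold", w), 0)
  expect_equal(at("gaussian_threshold", 0), 1)
  expect_gt(at("gaussian_threshold", 0.5 * w), 0)
  # difference of gaussians: 1 at the centre, negative surround
  expect_equal(at("diff_of_gaussians", 0), 1)
  expect_lt(at("diff_of_gaussians", 2 * w), 0)
  expect_equal(at("top_hat", 0.99 * w), 1)
  expect_equal(at("top_hat", 1.01 * w), 0)
})

test_that("difference-of-gaussians fields have ~zero total volume", {
  # numerical integral oracle over a disc much larger than the field
  w <- 0.05; r <- 1.5
  f <- function(d) (exp(-d^2 / (2 * w^2)) -
                      (1 / r^2) * exp(-d^2 / (2 * (r * w)^2))) / (1 - 1 / r^2)
  integrand <- function(d) 2 * pi * d * f(d)
  I <- integrate(integrand, 0, 1)$value
  expect_lt(abs(I), 1e-10)
})

test_that("geodesic place fields do not bleed through walls", {
  env <- fixture_environment("one_wall")
  ctr <- matrix(c(0.25, 0.3), 1)
  mk <- function(geom) PlaceCells(env, n = 1, centres = ctr,
                                  wall_geometry = geom)
  behind <- state_at(c(0.75, 0.3))  # other side of the wall
  r_geo <- drop(raw_rates(mk("geodesic"), behind))
  r_euc <- drop(raw_rates(mk("euclidean"), behind))
  r_los <- drop(raw_rates(mk("line_of_sight"), behind))
  expect_lt(r_geo, r_euc)
  expect_equal(r_los, 0)
  # same side of the wall: geodesic equals euclidean
  near <- state_at(c(0.3, 0.4))
  expect_equal(drop(raw_rates(mk("geodesic"), near)),
               drop(raw_rates(mk("euclidean"), near)), tolerance = 1e-12)
})

test_that("periodic place fields wrap around the boundary", {
  env <- fixture_environment("periodic_box")
  pc <- PlaceCells(env, n = 1, centres = matrix(c(0.05, 0.5), 1),
                   wall_geometry = "euclidean")
  r1 <- drop(raw_rates(pc, state_at(c(0.95, 0.5))))
  r2 <- drop(raw_rates(pc, state_at(c(0.15, 0.5))))
  expect_equal(r1, r2, tolerance = 1e-12)  # both are 0.1 m away (wrapped)
})

test_that("default place-cell centres cover the arena evenly", {
  set.seed(41)
  env <- Arena()
  pc <- PlaceCells(env, n = 25)
  g <- .ratemap_grid <- expand.grid(x = seq(0.025, 0.975, by = 0.05),
                                    y = seq(0.025, 0.975, by = 0.05))
  D <- sapply(seq_len(25), function(i)
    sqrt((g$x - pc$centres[i, 1])^2 + (g$y - pc$centres[i, 2])^2))
  expect_lt(max(apply(D, 1, min)), 2 * max(pc$widths))
})

test_that("grid cells peak at 1, trough at 0, with six-fold symmetry", {
  env <- Arena()
  gc <- GridCells(env, n = 1, gridscale = 0.3, orientation = 0,
                  phase_offset = 0)
  # all three cosine arguments vanish at the origin corner
  expect_equal(drop(raw_rates(gc, state_at(c(0, 0) + 1e-12))), 1,
               tolerance = 1e-6)
  gs <- GridCells(env, n = 1, gridscale = 0.3, orientation = 0,
                  phase_offset = 0, response = "three_shifted_cosines")
  expect_equal(drop(raw_rates(gs, state_at(c(0, 0) + 1e-12))), 1,
               tolerance = 1e-6)
  # shifted variant minimum is 0 (sum of three 60-degree cosines >= -3/2)
  rm <- explicit_rate_map(gs, dx = 0.005)
  expect_gte(min(rm$rates, na.rm = TRUE), -1e-9)
  expect_lt(min(rm$rates, na.rm = TRUE), 0.02)
  # autocorrelogram of the rectified map is invariant under 60-deg rotation
  rmr <- explicit_rate_map(GridCells(env, n = 1, gridscale = 0.4,
                                     orientation = 0.3, phase_offset = 1),
                           dx = 0.01)
  M <- ratemap_matrix(rmr) - mean(ratemap_matrix(rmr))
  ac <- function(sx, sy) {
    n <- nrow(M)
    i <- seq_len(n)
    ii <- i + sx; jj <- i + sy
    ok_i <- ii >= 1 & ii <= n; ok_j <- jj >= 1 & jj <= n
    cor(as.numeric(M[i[ok_i], i[ok_j]]),
        as.numeric(M[ii[ok_i], jj[ok_j]]))
  }
  r <- 30  # lag of 0.3 m
  a0 <- ac(r, 0)
  a60 <- ac(round(r * cos(pi / 3)), round(r * sin(pi / 3)))
  a120 <- ac(round(r * cos(2 * pi / 3)), round(r * sin(2 * pi / 3)))
  expect_lt(abs(a0 - a60), 0.06)
  expect_lt(abs(a0 - a120), 0.06)
})

test_that("vector-cell contributions peak at the tuning and fall off", {
  tun <- data.frame(d = 0.2, sigma_d = 0.05, phi = pi / 4, sigma_phi = 0.2,
                    kappa = 5)
  expect_equal(vector_cell_contribution(0.2, pi / 4, tun), 1)
  expect_lt(vector_cell_contribution(0.2, pi / 4 + pi, tun), 1e-4)
  expect_lt(vector_cell_contribution(0.5, pi / 4, tun), 1e-7)
})

test_that("egocentric responses rotate with the agent's heading", {
  env <- add_object(Arena(), c(0.7, 0.5))
  ov <- ObjectVectorCells(env, n = 1, reference_frame = "egocentric",
                          tunings = data.frame(d = 0.2, sigma_d = 0.05,
                                               phi = 0, sigma_phi = 0.2,
                                               kappa = 5),
                          object_tuning_type = 1)
  # object dead ahead at the tuning distance: peak
  r_ahead <- drop(raw_rates(ov, state_at(c(0.5, 0.5), head = c(1, 0))))
  expect_equal(r_ahead, 1, tolerance = 1e-12)
  # rotate the heading by delta: response shifts by exactly delta
  delta <- 0.6
  r_rot <- drop(raw_rates(ov, state_at(c(0.5, 0.5),
                                       head = c(cos(delta), sin(delta)))))
  tun2 <- data.frame(d = 0.2, sigma_d = 0.05, phi = -delta,
                     sigma_phi = 0.2, kappa = 5)
  expect_equal(r_rot, vector_cell_contribution(0.2, 0, tun2) /
                 vector_cell_contribution(0, 0, data.frame(
                   d = 0, sigma_d = 1, phi = 0, kappa = 0)),
               tolerance = 1e-9)
  # allocentric cells ignore heading entirely
  ova <- ObjectVectorCells(env, n = 1, reference_frame = "allocentric",
                           tunings = ov$tunings, object_tuning_type = 1)
  ra1 <- drop(raw_rates(ova, state_at(c(0.5, 0.5), head = c(1, 0))))
  ra2 <- drop(raw_rates(ova, state_at(c(0.5, 0.5), head = c(0, 1))))
  expect_equal(ra1, ra2)
})

test_that("BVC normalisation gives a rate-map maximum of 1", {
  set.seed(43)
  env <- Arena()
  bvc <- BoundaryVectorCells(env, n = 3, dx_norm = 0.02)
  rm <- explicit_rate_map(bvc, dx = 0.02)
  expect_equal(max(rm$rates, na.rm = TRUE), 1, tolerance = 1e-3)
  for (i in 1:3) expect_equal(max(rm$rates[, i], na.rm = TRUE), 1,
                              tolerance = 1e-3)
})

test_that("BVC responses respect symmetry and occlusion", {
  set.seed(44)
  env <- Arena()
  # rotationally symmetric cell (wide angular tuning) at box centre:
  # response invariant under 90-degree rotations of the position
  tun <- data.frame(d = 0.2, sigma_d = 0.06, phi = 0,
                    sigma_phi = 1e4, kappa = 1e-4)
  bvc <- BoundaryVectorCells(env, tunings = tun, dx_norm = 0.05)
  p <- c(0.3, 0.4)
  rot <- function(p) c(p[2], 1 - p[1])  # 90 deg about box centre
  r1 <- drop(raw_rates(bvc, state_at(p)))
  r2 <- drop(raw_rates(bvc, state_at(rot(p))))
  r3 <- drop(raw_rates(bvc, state_at(rot(rot(p)))))
  # kappa is small but nonzero, so symmetry is approximate at ~kappa level
  expect_equal(r1, r2, tolerance = 1e-3)
  expect_equal(r1, r3, tolerance = 1e-3)
  # an interior wall changes the first-hit distance for occluded rays
  envw <- add_wall(env, rbind(c(0.6, 0.3), c(0.6, 0.7)))
  bvcw <- BoundaryVectorCells(envw, tunings = tun, dx_norm = 0.05)
  rw <- drop(.bvc_unnormalised(bvcw, matrix(c(0.3, 0.5), 1), c(1, 0)))
  ro <- drop(.bvc_unnormalised(bvc, matrix(c(0.3, 0.5), 1), c(1, 0)))
  expect_gt(abs(rw - ro), 1e-3)
})

test_that("OVC additivity, type selectivity and occlusion", {
  tun <- data.frame(d = 0.2, sigma_d = 0.05, phi = 0, sigma_phi = 0.2,
                    kappa = 5)
  # no matching objects -> silent
  env0 <- add_object(Arena(), c(0.7, 0.5), type = 2)
  ov0 <- ObjectVectorCells(env0, tunings = tun, object_tuning_type = 1)
  expect_equal(drop(raw_rates(ov0, state_at(c(0.5, 0.5)))), 0)
  # agent at the tuning displacement from a single matching object: rate 1
  env1 <- add_object(Arena(), c(0.7, 0.5), type = 1)
  ov1 <- ObjectVectorCells(env1, tunings = tun, object_tuning_type = 1)
  expect_equal(drop(raw_rates(ov1, state_at(c(0.5, 0.5)))), 1,
               tolerance = 1e-12)
  # two coincident matching objects sum to 2
  env2 <- add_object(env1, c(0.7, 0.5), type = 1)
  ov2 <- ObjectVectorCells(env2, tunings = tun, object_tuning_type = 1)
  expect_equal(drop(raw_rates(ov2, state_at(c(0.5, 0.5)))), 2,
               tolerance = 1e-12)
  # a wall between agent and object silences the cell when walls occlude
  envw <- add_wall(env1, rbind(c(0.6, 0.3), c(0.6, 0.7)))
  ovw <- ObjectVectorCells(envw, tunings = tun, object_tuning_type = 1)
  expect_equal(drop(raw_rates(ovw, state_at(c(0.5, 0.5)))), 0)
  ovn <- ObjectVectorCells(envw, tunings = tun, object_tuning_type = 1,
                           walls_occlude = FALSE)
  expect_equal(drop(raw_rates(ovn, state_at(c(0.5, 0.5)))), 1,
               tolerance = 1e-12)
})

test_that("AVC tracks another agent with frame and occlusion rules", {
  tun <- data.frame(d = 0.2, sigma_d = 0.05, phi = 0, sigma_phi = 0.2,
                    kappa = 5)
  env <- Arena()
  avc <- AgentVectorCells(env, tunings = tun)
  r <- drop(raw_rates(avc, state_at(c(0.5, 0.5)), other_pos = c(0.7, 0.5)))
  expect_equal(r, 1, tolerance = 1e-12)
  # allocentric cells are invariant to the observer's heading
  r2 <- drop(raw_rates(avc, state_at(c(0.5, 0.5), head = c(0, 1)),
                       other_pos = c(0.7, 0.5)))
  expect_equal(r, r2)
  # occluding wall silences the cell
  envw <- add_wall(env, rbind(c(0.6, 0.3), c(0.6, 0.7)))
  avcw <- AgentVectorCells(envw, tunings = tun)
  expect_equal(drop(raw_rates(avcw, state_at(c(0.5, 0.5)),
                              other_pos = c(0.7, 0.5))), 0)
})

test_that("field-of-view tilings respect their specification", {
  fov <- build_field_of_view(distance_range = c(0.02, 0.4),
                             angle_range = c(0, 75),
                             spatial_resolution = 0.02, manifold = "diverging",
                             beta = 5)
  expect_true(all(fov$d >= 0.02 - 1e-9 & fov$d <= 0.4 + 1e-9))
  expect_true(all(abs(fov$phi) <= 75 * pi / 180 + 1e-9))
  # diverging: receptive fields grow strictly with distance
  by_row <- unique(fov[, c("d", "sigma_d")])
  by_row <- by_row[order(by_row$d), ]
  expect_true(all(diff(by_row$sigma_d) > 0))
  # approximately circular receptive fields: sigma_d = d * sigma_phi
  expect_all_close(fov$sigma_d, fov$d * fov$sigma_phi, 1e-9)
  # uniform manifold: constant resolution
  fovu <- build_field_of_view(manifold = "uniform")
  expect_true(all(abs(fovu$sigma_d - 0.02) < 1e-12))
  expect_error(build_field_of_view(distance_range = c(0.02, 0.03),
                                   spatial_resolution = 0.02), "coarse")
})

test_that("head direction cells: von Mises peak in 2D, sign cells in 1D", {
  env <- Arena()
  hdc <- HeadDirectionCells(env, n = 8)
  r <- drop(raw_rates(hdc, state_at(c(0.5, 0.5), head = c(1, 0))))
  expect_equal(r[1], 1)            # first cell prefers 0 rad
  expect_lt(max(r[-1]), 1)
  env1 <- Arena(dimensionality = "1D")
  hd1 <- HeadDirectionCells(env1)
  expect_equal(hd1$n, 2L)
  rr <- drop(raw_rates(hd1, list(pos = matrix(0.5), vel = 0.05)))
  expect_equal(rr, c(1, 0))
  rl <- drop(raw_rates(hd1, list(pos = matrix(0.5), vel = -0.05)))
  expect_equal(rl, c(0, 1))
})

test_that("velocity and speed cells scale with speed", {
  env <- Arena()
  vc <- VelocityCells(env, n = 4, speed_scale = 0.08)
  r <- drop(raw_rates(vc, state_at(c(0.5, 0.5), vel = c(0.08, 0))))
  expect_equal(r[1], 1)  # aligned cell at speed sigma_v
  r2 <- drop(raw_rates(vc, state_at(c(0.5, 0.5), vel = c(0.16, 0))))
  expect_equal(r2[1], 2)
  sc <- SpeedCell(env, speed_scale = 0.08)
  expect_equal(drop(raw_rates(sc, state_at(c(0.5, 0.5),
                                           vel = c(0.08, 0)))), 1)
  # 1D velocity cells: rectified, scaled by sigma_v + mu_v
  env1 <- Arena(dimensionality = "1D")
  v1 <- VelocityCells(env1, speed_scale = 0.16)
  rr <- drop(raw_rates(v1, list(pos = matrix(0.5), vel = 0.08)))
  expect_equal(rr, c(0.5, 0))
})

test_that("phase precession: preferred phase at entry, centre and exit", {
  env <- Arena()
  pc <- PhasePrecessingPlaceCells(env, n = 1,
                                  centres = matrix(c(0.5, 0.5), 1),
                                  widths = 0.2, wall_geometry = "euclidean")
  sigma_i <- 2 * 0.2  # gaussian field boundary
  vel <- c(0.08, 0)
  preferred_phase <- function(pos) {
    phases <- seq(0, 2 * pi, length.out = 721)[-721]
    ts <- phases / (2 * pi * pc$theta_freq)
    f <- vapply(ts, function(t)
      phase_precession_factor(pc, matrix(pos, 1), vel, t)[1, 1], 1)
    phases[which.max(f)]
  }
  beta <- pc$theta_beta
  # entering the field head-on (d = -sigma): peak at pi + beta*pi
  expect_equal(preferred_phase(c(0.5 - sigma_i, 0.5)), pi + beta * pi,
               tolerance = 0.02)
  # at the centre: pi
  expect_equal(preferred_phase(c(0.5, 0.5)), pi, tolerance = 0.02)
  # leaving: pi - beta*pi
  expect_equal(preferred_phase(c(0.5 + sigma_i, 0.5)), pi - beta * pi,
               tolerance = 0.02)
})

test_that("spike phases precess through a straight field crossing", {
  set.seed(46)
  env <- Arena()
  pc <- PhasePrecessingPlaceCells(env, n = 1,
                                  centres = matrix(c(0.5, 0.5), 1),
                                  widths = 0.1, max_fr = 30,
                                  wall_geometry = "euclidean")
  dt <- 0.002; v <- c(0.2, 0)
  ts <- seq(0, 0.6 / v[1], by = dt)
  xs <- 0.2 + v[1] * ts
  spikes_x <- c(); spikes_ph <- c()
  for (i in seq_along(ts)) {
    st <- list(t = ts[i], pos = matrix(c(xs[i], 0.5), 1), vel = v,
               head = c(1, 0))
    pc <- update_neurons(pc, st, dt)
    if (pc$spikes[1] == 1) {
      spikes_x <- c(spikes_x, xs[i])
      spikes_ph <- c(spikes_ph, (2 * pi * pc$theta_freq * ts[i]) %% (2 * pi))
    }
  }
  keep <- abs(spikes_x - 0.5) < 0.2
  # circular-linear trend: unwrap phases about pi and regress on position
  slope <- unname(coef(lm(spikes_ph[keep] ~ spikes_x[keep]))[2])
  expect_lt(slope, 0)  # phase advances (precesses) across the field
  # total precession spans roughly 2*beta*pi over the field diameter
  expect_equal(slope * 0.4, -2 * pc$theta_beta * pi, tolerance = 0.5)
})

test_that("random spatial neurons interpolate their GP targets", {
  set.seed(47)
  env <- Arena()
  rs <- RandomSpatialNeurons(env, n = 3, lengthscale = 0.2,
                             wall_geometry = "euclidean")
  # kernel dominance: with well-separated targets the weighted mean at a
  # target location reproduces its value (targets replaced by hand)
  iso <- rs
  iso$lengthscale <- 0.05
  iso$targets <- rbind(c(0.2, 0.2), c(0.8, 0.2), c(0.2, 0.8), c(0.8, 0.8))
  iso$target_values <- matrix(rnorm(12), 3, 4)
  r <- raw_rates(iso, list(pos = iso$targets[2, , drop = FALSE]))
  expect_equal(as.numeric(r), iso$target_values[, 2], tolerance = 1e-6)
  # variogram flattens at separations >> lengthscale
  g <- .ratemap_grid_pts <- as.matrix(expand.grid(seq(0.05, 0.95, by = 0.1),
                                                  seq(0.05, 0.95, by = 0.1)))
  vals <- raw_rates(rs, list(pos = g))
  D <- as.matrix(dist(g))
  v_near <- mean((outer(vals[, 1], vals[, 1], "-")^2)[D > 0 & D < 0.15])
  v_far <- mean((outer(vals[, 1], vals[, 1], "-")^2)[D > 0.6])
  expect_lt(v_near, v_far)
})

test_that("random spatial fields decorrelate across walls", {
  set.seed(48)
  env <- fixture_environment("one_wall")
  rs <- RandomSpatialNeurons(env, n = 40, lengthscale = 0.15,
                             wall_geometry = "geodesic",
                             target_spacing = 0.1)
  # point pairs straddling the wall are euclidean-near but geodesic-far
  a <- c(0.45, 0.2); b <- c(0.55, 0.2)   # 0.1 m apart, ~1 m around the wall
  c1 <- c(0.45, 0.8); c2 <- c(0.55, 0.8) # same separation, no wall between
  va <- as.numeric(raw_rates(rs, list(pos = matrix(a, 1))))
  vb <- as.numeric(raw_rates(rs, list(pos = matrix(b, 1))))
  v1 <- as.numeric(raw_rates(rs, list(pos = matrix(c1, 1))))
  v2 <- as.numeric(raw_rates(rs, list(pos = matrix(c2, 1))))
  expect_gt(cor(v1, v2), 0.9)        # smooth in open space
  expect_lt(cor(va, vb), cor(v1, v2))  # discontinuous across the wall
})

test_that("analytic raw rates stay in [0, 1] under fuzzing", {
  set.seed(49)
  env <- fixture_environment("one_wall")
  pops <- list(PlaceCells(env, n = 6),
               PlaceCells(env, n = 6, response = "gaussian_threshold"),
               PlaceCells(env, n = 6, response = "top_hat"),
               PlaceCells(env, n = 6, response = "one_hot"),
               GridCells(env, n = 6),
               GridCells(env, n = 6, response = "three_shifted_cosines"),
               HeadDirectionCells(env, n = 6))
  for (rep in 1:20) {
    p <- runif(2, 0.01, 0.99)
    th <- runif(1, 0, 2 * pi)
    st <- state_at(p, head = c(cos(th), sin(th)))
    for (pop in pops) {
      r <- raw_rates(pop, st)
      expect_true(all(r >= -1e-12 & r <= 1 + 1e-12))
    }
  }
})
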