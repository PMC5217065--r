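# Independent oracles and fixture builders used across the suite.

# Plane normal by SVD of the centred landmark triangle: the singular vector
# of smallest singular value is the normal. Independent of the package's
# cross-product route.
oracle_plane_normal <- function(A, B, C) {
  M <- rbind(A, B, C)
  M <- sweep(M, 2, colMeans(M))
  n <- svd(M)$v[, 3]
  if (n[3] > 0) n <- -n
  n / sqrt(sum(n^2))
}

oracle_dip_dipdir <- function(A, B, C) {
  n <- oracle_plane_normal(A, B, C)
  plunge <- asin(min(1, max(-1, -n[3]))) * 180 / pi
  dip <- 90 - plunge
  dd <- if (dip < 1e-9) 0 else (atan2(n[1], n[2]) * 180 / pi + 180) %% 360
  if (dip > 90 - 1e-9) dd <- dd %% 180
  c(dip = dip, dip_direction = dd)
}

# General-angle Rodrigues rotation matrix (axis as azimuth of a horizontal
# line), used at angle = pi as the overturn oracle.
oracle_rotation_matrix <- function(axis_az_deg, angle_rad) {
  a <- axis_az_deg * pi / 180
  u <- c(sin(a), cos(a), 0)
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

# Landmark triple lying exactly on a plane with the given dip/dip-direction.
plane_landmarks <- function(dip_deg, dip_direction_deg, scale = 10) {
  s <- as.numeric(coquina:::azimuth_to_horizontal((dip_direction_deg - 90) %% 360))
  d <- as.numeric(trend_plunge_to_cartesian(dip_direction_deg, dip_deg))
  list(A = c(1, 2, 3), B = c(1, 2, 3) + scale * s, C = c(1, 2, 3) + 0.7 * scale * d)
}

# Uniform random unit vectors on the lower hemisphere as trend/plunge, via
# area-preserving inverse sampling (z = -u, u ~ U(0,1)).
random_lines <- function(n) {
  z <- -stats::runif(n)
  r <- sqrt(1 - z^2)
  t <- stats::runif(n, 0, 2 * pi)
  coquina::cartesian_to_trend_plunge(cbind(r * sin(t), r * cos(t), z))
}

# Scene with exactly one shell at a given orientation, built through the
# generator so downstream stages see a genuine scene object.
single_ammonoid_scene <- function(diameter = 20, pole_trend = 335,
                                  pole_plunge = 76, seed = 1,
                                  block = c(60, 60, 60)) {
  cfg <- fabric_config(n_ammonoids = 1L, n_gastropods = 0L,
                       pole_mean_trend_plunge = c(pole_trend, pole_plunge),
                       pole_kappa = 1e9,
                       ammonoid_size = list(name = "lognormal",
                                            meanlog = log(diameter),
                                            sdlog = 1e-9,
                                            min = diameter - 0.1,
                                            max = diameter + 0.1))
  generate_scene(cfg, block_dims_mm = block, seed = seed)
}

single_gastropod_scene <- function(length_mm = 9, axis_trend = 153,
                                   axis_plunge = 24, seed = 1,
                                   block = c(60, 60, 60)) {
  cfg <- fabric_config(n_ammonoids = 0L, n_gastropods = 1L,
                       gastropod_axis_mean_trend_plunge = c(axis_trend, axis_plunge),
                       gastropod_axis_kappa = 1e9,
                       gastropod_size = list(name = "lognormal",
                                             meanlog = log(length_mm),
                                             sdlog = 1e-9,
                                             min = length_mm - 0.1,
                                             max = length_mm + 0.1))
  generate_scene(cfg, block_dims_mm = block, seed = seed)
}

# Angular distance between two lines treated as axes (degrees).
axial_angle_deg <- function(t1, p1, t2, p2) {
  v1 <- as.numeric(trend_plunge_to_cartesian(t1, p1))
  v2 <- as.numeric(trend_plunge_to_cartesian(t2, p2))
  acos(min(1, abs(sum(v1 * v2)))) * 180 / pi
}
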