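# Lower-hemisphere stereographic projection of lines and plane poles onto the
# unit disc: equal-area (Schmidt) and equal-angle (Wulff) variants, their
# exact inverses, and great-circle traces of planes.

#' Project lines onto the lower-hemisphere stereonet
#'
#' Equal-area (Schmidt): r = sqrt(2) sin((90 - plunge)/2), which equals 1 for
#' a horizontal line, so the hemisphere fills the unit disc exactly.
#' Equal-angle (Wulff): r = tan((90 - plunge)/2). In both, x = r sin(trend),
#' y = r cos(trend), North up, azimuths clockwise.
#'
#' @param trend_deg,plunge_deg Numeric vectors, degrees; plunge in `[0, 90]`.
#' @param method `"equal_area"` (default) or `"equal_angle"`.
#' @return Data frame with columns `x`, `y` inside the unit disc.
#' @export
project_lower_hemisphere <- function(trend_deg, plunge_deg,
                                     method = c("equal_area", "equal_angle")) {
  method <- match.arg(method)
  if (any(plunge_deg < -1e-9 | plunge_deg > 90 + 1e-9))
    stop("plunges must lie in [0, 90]")
  colat <- deg2rad(90 - pmin(90, pmax(0, plunge_deg)))
  # equal-area: r = sqrt(2) sin(colat/2) reaches exactly 1 at colat = 90 deg,
  # so horizontal lines plot on the primitive circle without rescaling
  r <- switch(method,
              equal_area = sqrt(2) * sin(colat / 2),
              equal_angle = tan(colat / 2))
  t <- deg2rad(trend_deg)
  data.frame(x = r * sin(t), y = r * cos(t))
}

#' Invert a stereonet point back to trend and plunge
#'
#' Exact inverse of [project_lower_hemisphere()] for the same method.
#'
#' @param x,y Coordinates in the unit disc (x^2 + y^2 <= 1).
#' @param method `"equal_area"` or `"equal_angle"`.
#' @return Data frame with columns `trend_deg`, `plunge_deg`.
#' @export
unproject <- function(x, y, method = c("equal_area", "equal_angle")) {
  method <- match.arg(method)
  r <- sqrt(x^2 + y^2)
  if (any(r > 1 + 1e-9)) stop("points must lie inside the unit disc")
  r <- pmin(1, r)
  colat <- switch(method,
                  equal_area = 2 * asin(r / sqrt(2)),
                  equal_angle = 2 * atan(r))
  plunge <- 90 - rad2deg(colat)
  trend <- rad2deg(atan2(x, y)) %% 360
  trend[r < 1e-15] <- 0
  data.frame(trend_deg = trend, plunge_deg = plunge)
}

#' Stereonet pole and great-circle trace of a plane
#'
#' The pole is the plane's downward normal projected as a line; the great
#' circle is the trace of the plane itself through the lower hemisphere,
#' sampled as a polyline from one strike end to the other.
#'
#' @param plane A `plane_orientation` (see [plane_orientation()]).
#' @param method Projection method, as in [project_lower_hemisphere()].
#' @param n_points Number of vertices of the great-circle polyline (>= 90).
#' @return List with `pole` (1-row data frame x, y) and `great_circle`
#'   (data frame of `n_points` rows), all within the unit disc.
#' @export
plane_to_pole_and_great_circle <- function(plane,
                                           method = c("equal_area", "equal_angle"),
                                           n_points = 181) {
  stopifnot(inherits(plane, "plane_orientation"), n_points >= 90)
  method <- match.arg(method)
  pole <- project_lower_hemisphere(plane$pole$trend_deg, plane$pole$plunge_deg,
                                   method)
  strike_az <- (plane$dip_direction_deg - 90) %% 360
  s <- as.numeric(azimuth_to_horizontal(strike_az))          # strike direction
  d <- as.numeric(trend_plunge_to_cartesian(plane$dip_direction_deg,
                                            plane$dip_deg)) # down-dip vector
  t <- seq(0, pi, length.out = n_points)
  v <- outer(cos(t), s) + outer(sin(t), d)   # lower-hemisphere arc in-plane
  # direct conversion (v already has z <= 0); no axial folding so the
  # polyline runs smoothly from one strike end to the other
  plunge <- rad2deg(asin(pmin(1, pmax(0, -v[, 3]))))
  trend <- rad2deg(atan2(v[, 1], v[, 2])) %% 360
  gc <- project_lower_hemisphere(trend, plunge, method)
  list(pole = pole, great_circle = gc)
}
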