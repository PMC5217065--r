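# Coordinate frame used throughout: right-handed, x = East, y = North, z = up.
# Azimuths in degrees clockwise from North; plunge/dip positive downward from
# horizontal. Angles are stored in degrees everywhere; radians are internal.

DEG <- pi / 180

deg2rad <- function(x) x * DEG
rad2deg <- function(x) x / DEG

#' Convert trend/plunge to a downward unit vector
#'
#' A line with plunge p and trend t (azimuth of its downward end) maps to the
#' Cartesian unit vector (cos p sin t, cos p cos t, -sin p) in an East, North,
#' up frame.
#'
#' @param trend_deg Azimuth of the downward end of the line, degrees clockwise
#'   from North. Recycled against `plunge_deg`.
#' @param plunge_deg Angle below horizontal, degrees in `[0, 90]`.
#' @return A numeric matrix with one row per line and columns `x`, `y`, `z`.
#' @seealso [cartesian_to_trend_plunge()] for the inverse.
#' @export
#' @examples
#' trend_plunge_to_cartesian(0, 0)    # horizontal, due North
#' trend_plunge_to_cartesian(90, 45)  # plunging 45 toward East
trend_plunge_to_cartesian <- function(trend_deg, plunge_deg) {
  n <- max(length(trend_deg), length(plunge_deg))
  t <- deg2rad(rep_len(trend_deg, n))
  p <- deg2rad(rep_len(plunge_deg, n))
  cbind(x = cos(p) * sin(t), y = cos(p) * cos(t), z = -sin(p))
}

#' Convert Cartesian vectors to trend and plunge
#'
#' Vectors are treated as axes: any vector pointing into the upper hemisphere
#' is replaced by its antipode, so the reported end always points downward
#' (plunge in `[0, 90]`). Horizontal axes have their trend normalised into
#' `[0, 180)`.
#'
#' @param v Numeric matrix with 3 columns (or a length-3 vector), any nonzero
#'   magnitude.
#' @return Data frame with columns `trend_deg`, `plunge_deg`.
#' @export
cartesian_to_trend_plunge <- function(v) {
  v <- to_matrix3(v)
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm < 1e-300)) stop("zero-length vector has no orientation")
  v <- v / nrm
  flip <- v[, 3] > 0
  v[flip, ] <- -v[flip, , drop = FALSE]
  plunge <- rad2deg(asin(pmin(1, pmax(-1, -v[, 3]))))
  trend <- rad2deg(atan2(v[, 1], v[, 2])) %% 360
  horiz <- plunge < 1e-9
  trend[horiz] <- trend[horiz] %% 180
  data.frame(trend_deg = trend, plunge_deg = plunge)
}

# Azimuth of the horizontal projection of vectors; NA where the projection is
# degenerate (|horizontal| below tol). Directed, in [0, 360).
horizontal_azimuth <- function(v, tol = 1e-12) {
  v <- to_matrix3(v)
  h <- sqrt(v[, 1]^2 + v[, 2]^2)
  az <- rad2deg(atan2(v[, 1], v[, 2])) %% 360
  az[h < tol] <- NA_real_
  az
}

to_matrix3 <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  if (ncol(v) != 3) stop("expected 3 columns (x, y, z)")
  v
}

# Smallest angle in degrees between two sets of vectors (directed). A
# single-row b is recycled against a.
angle_between_deg <- function(a, b) {
  a <- to_matrix3(a); b <- to_matrix3(b)
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  a <- a / sqrt(rowSums(a^2)); b <- b / sqrt(rowSums(b^2))
  rad2deg(acos(pmin(1, pmax(-1, rowSums(a * b)))))
}

# Minimal angular separation of two azimuths (degrees, in [0, 180]).
azimuth_diff_deg <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

# Unit horizontal vector for an azimuth.
azimuth_to_horizontal <- function(az_deg) {
  t <- deg2rad(az_deg)
  cbind(x = sin(t), y = cos(t), z = 0)
}
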