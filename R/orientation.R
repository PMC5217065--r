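# Orientation geometry: landmark sets -> lineation and sagittal-plane
# orientation parameters, plus stratigraphic overturn correction.
#
# Landmark scheme: A sits on the aperture margin, B on the margin opposite A
# (|A - B| is the maximum diameter / shell length), and C -- ammonoids only --
# is a third point on the margin off the A-B line, so that A, B, C span the
# sagittal (coiling) plane.

LENGTH_TOL <- 1e-6   # mm; |A-B| below this is a degenerate specimen
AREA_TOL <- 1e-6     # mm^2; triangle ABC area below this is collinear

#' Construct a landmark set
#'
#' @param A,B Numeric length-3 vectors, mm: the aperture-margin point and the
#'   margin point opposite it.
#' @param C Optional third sagittal-plane point (ammonoids); `NULL` for
#'   two-landmark (gastropod-style) specimens.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(A, B, C = NULL) {
  A <- as.numeric(A); B <- as.numeric(B)
  stopifnot(length(A) == 3, length(B) == 3)
  if (sqrt(sum((A - B)^2)) < LENGTH_TOL)
    stop("degenerate specimen: |A-B| below tolerance")
  if (!is.null(C)) {
    C <- as.numeric(C)
    stopifnot(length(C) == 3)
    if (triangle_area(A, B, C) < AREA_TOL)
      stop("degenerate plane: landmarks A, B, C are collinear")
  }
  structure(list(A = A, B = B, C = C), class = "landmark_set")
}

triangle_area <- function(A, B, C) {
  u <- B - A; w <- C - A
  n <- c(u[2] * w[3] - u[3] * w[2],
         u[3] * w[1] - u[1] * w[3],
         u[1] * w[2] - u[2] * w[1])
  sqrt(sum(n^2)) / 2
}

#' Lineation A:B from a landmark set
#'
#' The axis through A and B is reported as an undirected (axial) line: trend of
#' the downward end and plunge below horizontal. The aperture direction is kept
#' separately as the directed azimuth of the horizontal projection of the
#' vector B to A; it is `NA` when the axis is vertical.
#'
#' @param lm A [landmark_set()].
#' @return A `line_orientation` object with fields `trend_deg`, `plunge_deg`,
#'   `directed_azimuth_deg`, and `max_diameter_mm` (= |A-B|).
#' @export
lineation_from_landmarks <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  d <- lm$A - lm$B                     # points from B toward the aperture A
  len <- sqrt(sum(d^2))
  if (len < LENGTH_TOL) stop("degenerate specimen: |A-B| below tolerance")
  tp <- cartesian_to_trend_plunge(d)
  line_orientation(tp$trend_deg, tp$plunge_deg,
                   directed_azimuth_deg = horizontal_azimuth(d),
                   max_diameter_mm = len)
}

#' Sagittal plane A-B-C from a landmark set
#'
#' The plane normal is the cross product of (B - A) and (C - A), flipped to
#' point downward; dip and dip direction follow from the normal. The pole (the
#' downward normal reported as a line) satisfies pole trend = dip direction +
#' 180 (mod 360) and pole plunge = 90 - dip.
#'
#' @param lm A [landmark_set()] with C present.
#' @return A `plane_orientation` object.
#' @export
plane_from_landmarks <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  if (is.null(lm$C)) stop("plane orientation needs landmark C")
  u <- lm$B - lm$A; w <- lm$C - lm$A
  n <- c(u[2] * w[3] - u[3] * w[2],
         u[3] * w[1] - u[1] * w[3],
         u[1] * w[2] - u[2] * w[1])
  if (sqrt(sum(n^2)) < 2 * AREA_TOL)
    stop("degenerate plane: landmarks A, B, C are collinear")
  plane_from_normal(n)
}

#' Line orientation (trend/plunge, optional directed azimuth)
#'
#' @param trend_deg Azimuth of the downward end, degrees.
#' @param plunge_deg Plunge below horizontal, degrees in `[0, 90]`.
#' @param directed_azimuth_deg Optional directed azimuth (aperture direction).
#' @param max_diameter_mm Optional length carried along from the landmarks.
#' @return Object of class `line_orientation`.
#' @export
line_orientation <- function(trend_deg, plunge_deg, directed_azimuth_deg = NA_real_,
                             max_diameter_mm = NA_real_) {
  stopifnot(plunge_deg >= -1e-9, plunge_deg <= 90 + 1e-9)
  trend_deg <- trend_deg %% 360
  plunge_deg <- pmin(90, pmax(0, plunge_deg))
  if (plunge_deg < 1e-9) trend_deg <- trend_deg %% 180
  structure(list(trend_deg = trend_deg, plunge_deg = plunge_deg,
                 directed_azimuth_deg = directed_azimuth_deg %% 360,
                 max_diameter_mm = max_diameter_mm),
            class = "line_orientation")
}

#' Plane orientation (dip / dip direction, with pole)
#'
#' @param dip_deg Dip in `[0, 90]` degrees.
#' @param dip_direction_deg Azimuth of steepest descent, degrees.
#' @return Object of class `plane_orientation` with a `pole` field (a
#'   `line_orientation`). The pole stored here keeps the exact antipodal
#'   relation to `dip_direction_deg`, including for vertical planes.
#' @export
plane_orientation <- function(dip_deg, dip_direction_deg) {
  stopifnot(dip_deg >= -1e-9, dip_deg <= 90 + 1e-9)
  dip_deg <- pmin(90, pmax(0, dip_deg))
  if (dip_deg > 90 - 1e-9) dip_direction_deg <- dip_direction_deg %% 180
  dip_direction_deg <- dip_direction_deg %% 360
  pole <- structure(list(trend_deg = (dip_direction_deg + 180) %% 360,
                         plunge_deg = 90 - dip_deg,
                         directed_azimuth_deg = NA_real_,
                         max_diameter_mm = NA_real_),
                    class = "line_orientation")
  structure(list(dip_deg = dip_deg, dip_direction_deg = dip_direction_deg,
                 pole = pole),
            class = "plane_orientation")
}

# Plane orientation from any (not necessarily unit or downward) normal vector.
plane_from_normal <- function(n) {
  n <- as.numeric(n)
  n <- n / sqrt(sum(n^2))
  if (n[3] > 0) n <- -n
  pole_plunge <- rad2deg(asin(pmin(1, pmax(-1, -n[3]))))
  dip <- 90 - pole_plunge
  if (dip < 1e-9) {
    dip_dir <- 0    # horizontal plane: dip direction undefined; normalised to 0
  } else {
    pole_trend <- rad2deg(atan2(n[1], n[2])) %% 360
    dip_dir <- (pole_trend + 180) %% 360
    if (dip > 90 - 1e-9) dip_dir <- dip_dir %% 180  # vertical plane tie: [0, 180)
  }
  plane_orientation(dip, dip_dir)
}

#' Stratigraphic overturn correction
#'
#' Restores orientations measured in an overturned bed by rotating them 180
#' degrees about a horizontal axis (the fold strike). The rotation matrix for a
#' half-turn about unit axis u is 2uu' - I. Applying the correction twice
#' returns the input exactly. Undirected lines and planes whose trend is
#' perpendicular to the axis are invariant; directed azimuths a map to
#' 2*axis - a (mod 360).
#'
#' @param x A `line_orientation` or `plane_orientation`.
#' @param strike_axis_deg Azimuth of the horizontal rotation axis, degrees.
#' @return Object of the same class as `x`.
#' @export
correct_overturn <- function(x, strike_axis_deg) UseMethod("correct_overturn")

#' @export
correct_overturn.line_orientation <- function(x, strike_axis_deg) {
  v <- rotate_half_turn(trend_plunge_to_cartesian(x$trend_deg, x$plunge_deg),
                        strike_axis_deg)
  tp <- cartesian_to_trend_plunge(v)
  az <- x$directed_azimuth_deg
  if (!is.na(az)) az <- (2 * strike_axis_deg - az) %% 360
  line_orientation(tp$trend_deg, tp$plunge_deg, directed_azimuth_deg = az,
                   max_diameter_mm = x$max_diameter_mm)
}

#' @export
correct_overturn.plane_orientation <- function(x, strike_axis_deg) {
  pole <- x$pole
  v <- rotate_half_turn(trend_plunge_to_cartesian(pole$trend_deg, pole$plunge_deg),
                        strike_axis_deg)
  plane_from_normal(as.numeric(v))
}

# 180-degree rotation of row vectors about the horizontal axis with the given
# azimuth: R v = 2 (u . v) u - v.
rotate_half_turn <- function(v, axis_az_deg) {
  v <- to_matrix3(v)
  u <- as.numeric(azimuth_to_horizontal(axis_az_deg))
  d <- as.numeric(v %*% u)
  2 * outer(d, u) - v
}

#' @export
print.line_orientation <- function(x, ...) {
  cat(sprintf("<line_orientation> %05.1f/%04.1f (trend/plunge)",
              x$trend_deg, x$plunge_deg))
  if (!is.na(x$directed_azimuth_deg))
    cat(sprintf(", aperture azimuth %05.1f", x$directed_azimuth_deg))
  if (!is.na(x$max_diameter_mm))
    cat(sprintf(", |A-B| %.2f mm", x$max_diameter_mm))
  cat("\n")
  invisible(x)
}

#' @export
print.plane_orientation <- function(x, ...) {
  cat(sprintf("<plane_orientation> dip %04.1f toward %05.1f (pole %05.1f/%04.1f)\n",
              x$dip_deg, x$dip_direction_deg,
              x$pole$trend_deg, x$pole$plunge_deg))
  invisible(x)
}

#' Orientation table from a landmark table
#'
#' Applies [lineation_from_landmarks()] and (where landmark C is present)
#' [plane_from_landmarks()] to every row of a landmark table, yielding the
#' per-specimen orientation parameters used by the fabric statistics.
#'
#' @param lm_table Data frame with columns `specimen_id`, `taxon`,
#'   `Ax,Ay,Az,Bx,By,Bz`, optionally `Cx,Cy,Cz` (NA where C is absent), and
#'   `slice_count`.
#' @param thresholds Named list of slice-count eligibility thresholds, see
#'   [eligibility_filter()].
#' @return Data frame with one row per specimen: `specimen_id`, `taxon`,
#'   `trend_deg`, `plunge_deg`, `aperture_azimuth_deg`, `dip_deg`,
#'   `dip_direction_deg`, `pole_trend_deg`, `pole_plunge_deg`,
#'   `max_diameter_mm`, `slice_count`, and logical eligibility flags.
#' @export
measure_orientations <- function(lm_table,
                                 thresholds = list(lineation = 6L, plane = 3L,
                                                   gastropod = 2L)) {
  n <- nrow(lm_table)
  out <- data.frame(
    specimen_id = lm_table$specimen_id,
    taxon = lm_table$taxon,
    trend_deg = NA_real_, plunge_deg = NA_real_,
    aperture_azimuth_deg = NA_real_,
    dip_deg = NA_real_, dip_direction_deg = NA_real_,
    pole_trend_deg = NA_real_, pole_plunge_deg = NA_real_,
    max_diameter_mm = NA_real_,
    slice_count = lm_table$slice_count,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    A <- as.numeric(lm_table[i, c("Ax", "Ay", "Az")])
    B <- as.numeric(lm_table[i, c("Bx", "By", "Bz")])
    C <- NULL
    if (all(c("Cx", "Cy", "Cz") %in% names(lm_table))) {
      Cv <- as.numeric(lm_table[i, c("Cx", "Cy", "Cz")])
      if (!anyNA(Cv)) C <- Cv
    }
    lm <- landmark_set(A, B, C)
    ln <- lineation_from_landmarks(lm)
    out$trend_deg[i] <- ln$trend_deg
    out$plunge_deg[i] <- ln$plunge_deg
    out$aperture_azimuth_deg[i] <- ln$directed_azimuth_deg
    out$max_diameter_mm[i] <- ln$max_diameter_mm
    if (!is.null(C)) {
      pl <- plane_from_landmarks(lm)
      out$dip_deg[i] <- pl$dip_deg
      out$dip_direction_deg[i] <- pl$dip_direction_deg
      out$pole_trend_deg[i] <- pl$pole$trend_deg
      out$pole_plunge_deg[i] <- pl$pole$plunge_deg
    }
  }
  amm <- out$taxon == "ammonoid"
  out$lineation_eligible <- amm & out$slice_count >= thresholds$lineation
  out$plane_eligible <- amm & out$slice_count >= thresholds$plane &
    !is.na(out$dip_deg)
  out$gastropod_eligible <- !amm & out$slice_count >= thresholds$gastropod
  out
}
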