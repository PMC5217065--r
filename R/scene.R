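# Synthetic shell beds: ground-truth 3D scenes of planispiral (ammonoid) and
# helical (gastropod) shells with controlled orientation fabrics, sizes and
# abundances. An ammonoid is idealised as a solid disc (the convex hull of the
# annular shell: outer diameter = maximum diameter, thickness = whorl width)
# with a marked aperture point on its rim; a gastropod as a solid cone from
# apex to aperture along the shell axis. Shells are treated through the
# landmarks A, B, C only, so no richer morphology is modelled.

#' Fabric configuration for a synthetic shell bed
#'
#' Defaults reproduce the study conditions of the reference block this package
#' emulates: 3,253 ammonoids to 211 gastropods (about 15:1), ammonoid maximum
#' diameters 1.5-27.7 mm, gastropod shell lengths 2.8-11.3 mm, sagittal planes
#' imbricated about 14 degrees toward 155 (pole 335/76), and a bimodal
#' NNW/SSE aperture fabric (wrapped-normal mixture with modes 180 degrees
#' apart at 155 and 335).
#'
#' @param n_ammonoids,n_gastropods Shell counts (>= 0).
#' @param pole_mean_trend_plunge Mean sagittal-plane pole `(trend, plunge)` in
#'   degrees; the default 335/76 is the pole of a plane dipping 14 toward 155.
#' @param pole_kappa Fisher concentration of the sagittal poles. The default 3
#'   yields a preferred orientation (100 R/n) near the mid-60s percent.
#' @param aperture_mode_azimuths Two mixture mode azimuths, 180 degrees apart.
#' @param aperture_mix Proportion of apertures drawn from the first mode.
#' @param aperture_sd_deg Wrapped-normal spread about each mode, degrees.
#' @param gastropod_axis_mean_trend_plunge,gastropod_axis_kappa Fisher mean
#'   and concentration of the gastropod shell axes (default 153/24, kappa 4).
#' @param ammonoid_size,gastropod_size Size distributions: lists with `name`
#'   ("lognormal"), `meanlog`, `sdlog`, `min`, `max` (mm); sampled by
#'   truncation to `[min, max]`.
#' @param whorl_fraction Whorl width as a fraction of diameter (free
#'   parameter; tube width statistics are not constrained by the landmarks).
#' @param packing `"shell_supported"` (interpenetration allowed, the default:
#'   the bed is shell-supported and contacts are irrelevant to orientation
#'   statistics) or `"matrix_supported"` (minimum-spacing rejection).
#' @param min_spacing_mm Minimum centre spacing under matrix-supported
#'   packing, mm.
#' @return Object of class `fabric_config`.
#' @export
fabric_config <- function(n_ammonoids = 3253L,
                          n_gastropods = 211L,
                          pole_mean_trend_plunge = c(335, 76),
                          pole_kappa = 3,
                          aperture_mode_azimuths = c(155, 335),
                          aperture_mix = 0.5,
                          aperture_sd_deg = 30,
                          gastropod_axis_mean_trend_plunge = c(153, 24),
                          gastropod_axis_kappa = 4,
                          ammonoid_size = list(name = "lognormal",
                                               meanlog = log(8), sdlog = 0.5,
                                               min = 1.5, max = 27.7),
                          gastropod_size = list(name = "lognormal",
                                                meanlog = log(6), sdlog = 0.35,
                                                min = 2.8, max = 11.3),
                          whorl_fraction = 0.25,
                          packing = c("shell_supported", "matrix_supported"),
                          min_spacing_mm = 0) {
  packing <- match.arg(packing)
  stopifnot(n_ammonoids >= 0, n_gastropods >= 0,
            pole_kappa > 0, gastropod_axis_kappa > 0,
            aperture_mix >= 0, aperture_mix <= 1,
            aperture_sd_deg >= 0, whorl_fraction > 0, whorl_fraction < 1,
            length(pole_mean_trend_plunge) == 2,
            length(aperture_mode_azimuths) == 2)
  if (azimuth_diff_deg(aperture_mode_azimuths[1],
                       (aperture_mode_azimuths[2] + 180) %% 360) > 1e-6)
    warning("aperture modes are not 180 degrees apart; the fabric will not be bimodal-axial")
  structure(list(n_ammonoids = as.integer(n_ammonoids),
                 n_gastropods = as.integer(n_gastropods),
                 pole_mean_trend_plunge = as.numeric(pole_mean_trend_plunge),
                 pole_kappa = pole_kappa,
                 aperture_mode_azimuths = as.numeric(aperture_mode_azimuths),
                 aperture_mix = aperture_mix,
                 aperture_sd_deg = aperture_sd_deg,
                 gastropod_axis_mean_trend_plunge =
                   as.numeric(gastropod_axis_mean_trend_plunge),
                 gastropod_axis_kappa = gastropod_axis_kappa,
                 ammonoid_size = ammonoid_size,
                 gastropod_size = gastropod_size,
                 whorl_fraction = whorl_fraction,
                 packing = packing,
                 min_spacing_mm = min_spacing_mm),
            class = "fabric_config")
}

#' Generate a synthetic shell-bed scene
#'
#' Draws shell sizes, positions and orientations from the distributions in a
#' [fabric_config()] and places all shells fully inside the block. The result
#' is reproducible bit-for-bit from `(config, seed)`.
#'
#' @param config A [fabric_config()].
#' @param block_dims_mm Block dimensions `(x, y, z)` in mm, x East, y North,
#'   z up. The default 150 x 140 x 45 is the reference block laid out in bed
#'   coordinates: the 45 mm dimension is the bed thickness (vertical) and the
#'   140 mm dimension the horizontal grinding axis.
#' @param seed Integer seed.
#' @return Object of class `scene`: `shells` (one row per shell with centre,
#'   size, true orientation parameters and true landmark points),
#'   `block_dims_mm`, `seed`, `config`.
#' @export
generate_scene <- function(config, block_dims_mm = c(150, 140, 45), seed = 1L) {
  stopifnot(inherits(config, "fabric_config"), length(block_dims_mm) == 3,
            all(block_dims_mm > 0))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)

  n_a <- config$n_ammonoids
  n_g <- config$n_gastropods
  n <- n_a + n_g
  shells <- empty_shell_table(n)
  if (n == 0) {
    return(structure(list(shells = shells, block_dims_mm = block_dims_mm,
                          seed = as.integer(seed), config = config),
                     class = "scene"))
  }
  shells$id <- seq_len(n)
  shells$taxon <- rep(c("ammonoid", "gastropod"), c(n_a, n_g))

  # -- sizes ----------------------------------------------------------------
  if (n_a > 0)
    shells$diameter_mm[1:n_a] <- sample_truncated_size(config$ammonoid_size, n_a)
  if (n_g > 0)
    shells$diameter_mm[n_a + 1:n_g] <- sample_truncated_size(config$gastropod_size, n_g)
  shells$whorl_width_mm <- config$whorl_fraction * shells$diameter_mm

  # -- orientations ---------------------------------------------------------
  ap <- sample_aperture_azimuths(config, n)
  if (n_a > 0) {
    poles <- sample_fisher_lines(config$pole_mean_trend_plunge,
                                 config$pole_kappa, n_a)
    # report poles as downward axes
    flip <- poles[, 3] > 0
    poles[flip, ] <- -poles[flip, , drop = FALSE]
    shells[1:n_a, c("pole_x", "pole_y", "pole_z")] <- poles
  }
  if (n_g > 0) {
    axes <- sample_fisher_lines(config$gastropod_axis_mean_trend_plunge,
                                config$gastropod_axis_kappa, n_g)
    shells[n_a + 1:n_g, c("axis_x", "axis_y", "axis_z")] <- axes
  }

  # -- placement ------------------------------------------------------------
  half <- ifelse(shells$taxon == "ammonoid",
                 sqrt((shells$diameter_mm / 2)^2 + (shells$whorl_width_mm / 2)^2),
                 shells$diameter_mm / 2 + 1e-9)
  if (any(2 * half >= block_dims_mm[1]) || any(2 * half >= block_dims_mm[2]) ||
      any(2 * half >= block_dims_mm[3]))
    stop("block too small to contain the largest shell")
  centers <- place_centers(n, half, block_dims_mm, config$packing,
                           config$min_spacing_mm, shells$diameter_mm)
  shells[, c("cx", "cy", "cz")] <- centers

  # -- landmarks and true orientation parameters ----------------------------
  for (i in seq_len(n)) {
    ctr <- as.numeric(shells[i, c("cx", "cy", "cz")])
    R <- shells$diameter_mm[i] / 2
    if (shells$taxon[i] == "ammonoid") {
      p <- as.numeric(shells[i, c("pole_x", "pole_y", "pole_z")])
      u <- inplane_direction(p, ap[i])
      w <- cross3(p, u)
      A <- ctr + R * u; B <- ctr - R * u; C <- ctr + R * w
      shells[i, c("Ax", "Ay", "Az")] <- A
      shells[i, c("Bx", "By", "Bz")] <- B
      shells[i, c("Cx", "Cy", "Cz")] <- C
      shells$aperture_azimuth_deg[i] <- horizontal_azimuth(A - B)
    } else {
      v <- as.numeric(shells[i, c("axis_x", "axis_y", "axis_z")])
      # orient the aperture end of the axis toward the drawn mixture azimuth
      az_v <- horizontal_azimuth(v)
      dir <- if (!is.na(az_v) && azimuth_diff_deg(az_v, ap[i]) > 90) -v else v
      A <- ctr + R * dir; B <- ctr - R * dir
      shells[i, c("Ax", "Ay", "Az")] <- A
      shells[i, c("Bx", "By", "Bz")] <- B
      shells$aperture_azimuth_deg[i] <- horizontal_azimuth(A - B)
    }
  }
  structure(list(shells = shells, block_dims_mm = as.numeric(block_dims_mm),
                 seed = as.integer(seed), config = config),
            class = "scene")
}

empty_shell_table <- function(n) {
  cols <- c("id", "taxon", "cx", "cy", "cz", "diameter_mm", "whorl_width_mm",
            "pole_x", "pole_y", "pole_z", "axis_x", "axis_y", "axis_z",
            "aperture_azimuth_deg",
            "Ax", "Ay", "Az", "Bx", "By", "Bz", "Cx", "Cy", "Cz")
  out <- as.data.frame(matrix(NA_real_, nrow = n, ncol = length(cols),
                              dimnames = list(NULL, cols)))
  out$id <- integer(n)
  out$taxon <- character(n)
  out
}

sample_truncated_size <- function(dist, n) {
  stopifnot(identical(dist$name, "lognormal"), dist$min > 0, dist$max > dist$min)
  out <- numeric(0)
  guard <- 0
  while (length(out) < n) {
    x <- stats::rlnorm(2 * n, dist$meanlog, dist$sdlog)
    out <- c(out, x[x >= dist$min & x <= dist$max])
    guard <- guard + 1
    if (guard > 1000)
      stop("size distribution rejects nearly all draws; check min/max against meanlog/sdlog")
  }
  out[seq_len(n)]
}

sample_aperture_azimuths <- function(config, n) {
  pick <- stats::runif(n) < config$aperture_mix
  ctr <- ifelse(pick, config$aperture_mode_azimuths[1],
                config$aperture_mode_azimuths[2])
  (ctr + stats::rnorm(n, 0, config$aperture_sd_deg)) %% 360
}

place_centers <- function(n, half, dims, packing, min_spacing, diameter) {
  lo <- cbind(half, half, half)
  hi <- cbind(dims[1] - half, dims[2] - half, dims[3] - half)
  draw <- function(k, idx) {
    cbind(stats::runif(k, lo[idx, 1], hi[idx, 1]),
          stats::runif(k, lo[idx, 2], hi[idx, 2]),
          stats::runif(k, lo[idx, 3], hi[idx, 3]))
  }
  if (packing == "shell_supported" || min_spacing <= 0)
    return(draw(n, seq_len(n)))
  centers <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in 1:200) {
      cand <- draw(1, i)
      if (i == 1 || all(sqrt(rowSums(sweep(centers[seq_len(i - 1), , drop = FALSE],
                                           2, cand, "-")^2)) >= min_spacing)) {
        centers[i, ] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      placed <- i - 1
      vol_frac <- sum(pi / 6 * diameter[seq_len(placed)]^3) / prod(dims)
      stop(sprintf(paste0("infeasible packing: placed %d of %d shells under ",
                          "min spacing %.2f mm (achieved volume fraction %.4f)"),
                   placed, n, min_spacing, vol_frac))
    }
  }
  centers
}

# In-plane unit direction of a disc (pole p) whose horizontal azimuth equals
# az: u is proportional to p_z * h - (h . p) * zhat, sign-fixed so the
# horizontal part points toward az. Falls back to the projection of h onto the
# plane when the disc is vertical (p_z ~ 0), where the requested azimuth may
# not be attainable exactly.
inplane_direction <- function(p, az_deg) {
  h <- as.numeric(azimuth_to_horizontal(az_deg))
  if (abs(p[3]) > 1e-9) {
    u <- p[3] * h - sum(h * p) * c(0, 0, 1)
    u <- u * sign(p[3])
  } else {
    u <- h - sum(h * p) * p
    if (sqrt(sum(u^2)) < 1e-12) u <- cross3(p, c(0, 0, 1))
  }
  u / sqrt(sum(u^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Ground-truth orientation table of a scene
#'
#' One row per shell with the true (generator) orientation parameters, the
#' quantities the reconstruction pipeline estimates: lineation trend/plunge of
#' the A:B axis, sagittal-plane dip/dip-direction and pole (ammonoids),
#' aperture azimuth, and diameter.
#'
#' @param scene A [generate_scene()] result.
#' @return Data frame with columns `id`, `taxon`, `trend_deg`, `plunge_deg`,
#'   `aperture_azimuth_deg`, `dip_deg`, `dip_direction_deg`, `pole_trend_deg`,
#'   `pole_plunge_deg`, `diameter_mm`.
#' @export
ground_truth_table <- function(scene) {
  stopifnot(inherits(scene, "scene"))
  sh <- scene$shells
  n <- nrow(sh)
  out <- data.frame(id = sh$id, taxon = sh$taxon,
                    trend_deg = rep(NA_real_, n), plunge_deg = rep(NA_real_, n),
                    aperture_azimuth_deg = sh$aperture_azimuth_deg,
                    dip_deg = rep(NA_real_, n),
                    dip_direction_deg = rep(NA_real_, n),
                    pole_trend_deg = rep(NA_real_, n),
                    pole_plunge_deg = rep(NA_real_, n),
                    diameter_mm = sh$diameter_mm,
                    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  ab <- as.matrix(sh[, c("Ax", "Ay", "Az")]) - as.matrix(sh[, c("Bx", "By", "Bz")])
  tp <- cartesian_to_trend_plunge(ab)
  out$trend_deg <- tp$trend_deg
  out$plunge_deg <- tp$plunge_deg
  amm <- which(sh$taxon == "ammonoid")
  for (i in amm) {
    pl <- plane_from_normal(as.numeric(sh[i, c("pole_x", "pole_y", "pole_z")]))
    out$dip_deg[i] <- pl$dip_deg
    out$dip_direction_deg[i] <- pl$dip_direction_deg
    out$pole_trend_deg[i] <- pl$pole$trend_deg
    out$pole_plunge_deg[i] <- pl$pole$plunge_deg
  }
  out
}

#' @export
print.scene <- function(x, ...) {
  tab <- table(factor(x$shells$taxon, levels = c("ammonoid", "gastropod")))
  cat(sprintf("<scene> %d shells (%d ammonoids, %d gastropods) in %g x %g x %g mm block, seed %d\n",
              nrow(x$shells), tab[["ammonoid"]], tab[["gastropod"]],
              x$block_dims_mm[1], x$block_dims_mm[2], x$block_dims_mm[3],
              x$seed))
  invisible(x)
}
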