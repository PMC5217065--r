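# Fisher (von Mises-Fisher on the sphere, p = 3) sampling and summary
# statistics: mean direction, resultant length, concentration, the alpha95
# cone of confidence, and the preferred-orientation percentage.

#' Sample unit vectors from a Fisher distribution
#'
#' Draws axes about a mean direction given as trend/plunge, using the exact
#' inverse-CDF for the Fisher colatitude: with U uniform on (0,1),
#' cos(theta) = 1 + log(U + (1 - U) exp(-2 kappa)) / kappa, longitude uniform,
#' then rotated so the pole of the construction frame maps onto the mean.
#'
#' @param mean_trend_plunge Length-2 numeric `(trend, plunge)` in degrees.
#' @param kappa Fisher concentration, > 0. Large kappa concentrates the sample
#'   around the mean; kappa near 0 approaches the uniform sphere.
#' @param n Number of vectors to draw.
#' @param seed Optional integer seed (local RNG state; the caller's RNG is
#'   restored on exit when a seed is given).
#' @return An `n` x 3 matrix of unit vectors (East, North, up frame).
#' @export
sample_fisher_lines <- function(mean_trend_plunge, kappa, n, seed = NULL) {
  stopifnot(length(mean_trend_plunge) == 2, n >= 0)
  if (!is.numeric(kappa) || length(kappa) != 1 || !is.finite(kappa) || kappa <= 0)
    stop("kappa must be a positive number")
  if (n == 0) return(matrix(numeric(0), ncol = 3,
                            dimnames = list(NULL, c("x", "y", "z"))))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  u <- stats::runif(n)
  # log1p form is stable for large kappa, where exp(-2 kappa) underflows
  ct <- 1 + log1p(-(1 - u) * (1 - exp(-2 * kappa))) / kappa
  ct <- pmin(1, pmax(-1, ct))
  st <- sqrt(1 - ct^2)
  phi <- stats::runif(n, 0, 2 * pi)
  local <- cbind(st * cos(phi), st * sin(phi), ct)  # about +z
  mu <- as.numeric(trend_plunge_to_cartesian(mean_trend_plunge[1],
                                             mean_trend_plunge[2]))
  v <- local %*% t(rotation_to(mu))
  colnames(v) <- c("x", "y", "z")
  v
}

# Rotation matrix taking +z onto the unit vector mu (Rodrigues form; any
# rotation with that property serves, longitude being uniform).
rotation_to <- function(mu) {
  z <- c(0, 0, 1)
  c_ <- sum(z * mu)
  if (c_ > 1 - 1e-15) return(diag(3))
  if (c_ < -1 + 1e-15) return(diag(c(1, -1, -1)))
  axis <- c(z[2] * mu[3] - z[3] * mu[2],
            z[3] * mu[1] - z[1] * mu[3],
            z[1] * mu[2] - z[2] * mu[1])
  s <- sqrt(sum(axis^2))
  axis <- axis / s
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Fisher statistics for a sample of lines
#'
#' Computes the spherical mean direction, resultant length R, concentration
#' estimate kappa = (n - 1)/(n - R), the cone of confidence about the mean
#' (half-angle alpha95 at the given significance), and the preferred
#' orientation percentage 100 R/n -- 100 would indicate perfectly parallel
#' lines.
#'
#' Lines are treated as axes: before averaging, each unit vector is flipped if
#' needed so all lie in the hemisphere around the dominant eigenvector of the
#' orientation tensor. The result is therefore invariant under 180-degree
#' flips of any subset of the input.
#'
#' @param trend_deg,plunge_deg Numeric vectors, degrees; plunges in `[0, 90]`.
#' @param significance Cone significance level in (0, 1); 0.05 gives the
#'   conventional 95 percent cone.
#' @return Object of class `fisher_stats`: `mean_trend_deg`, `mean_plunge_deg`,
#'   `resultant_length_R`, `n`, `kappa_hat`, `alpha95_deg` (NA for n < 3), and
#'   `preferred_orientation_pct`.
#' @references Fisher, N.I., Lewis, T. & Embleton, B.J.J. (1987) Statistical
#'   Analysis of Spherical Data. Cambridge University Press.
#' @export
fisher_statistics <- function(trend_deg, plunge_deg, significance = 0.05) {
  stopifnot(length(trend_deg) == length(plunge_deg),
            significance > 0, significance < 1)
  n <- length(trend_deg)
  if (n < 1) stop("need at least one line")
  if (any(plunge_deg < -1e-9 | plunge_deg > 90 + 1e-9))
    stop("plunges must lie in [0, 90]")
  v <- trend_plunge_to_cartesian(trend_deg, plunge_deg)
  v <- align_axes(v)
  res <- colSums(v)
  R <- sqrt(sum(res^2))
  mean_tp <- if (R > 1e-12) cartesian_to_trend_plunge(res) else
    data.frame(trend_deg = NA_real_, plunge_deg = NA_real_)
  kappa_hat <- if (n > 1 && n - R > 1e-12) (n - 1) / (n - R) else Inf
  alpha95 <- NA_real_
  if (n >= 3 && R > 1e-12) {
    ca <- 1 - (n - R) / R * ((1 / significance)^(1 / (n - 1)) - 1)
    alpha95 <- rad2deg(acos(pmin(1, pmax(-1, ca))))
  }
  structure(list(mean_trend_deg = mean_tp$trend_deg,
                 mean_plunge_deg = mean_tp$plunge_deg,
                 resultant_length_R = R,
                 n = n,
                 kappa_hat = kappa_hat,
                 alpha95_deg = alpha95,
                 significance = significance,
                 preferred_orientation_pct = 100 * R / n),
            class = "fisher_stats")
}

# Flip axes into a common hemisphere: the one about the dominant eigenvector
# of the orientation tensor sum(v v'). Exact invariance under per-axis sign
# flips follows because v v' is sign-free.
align_axes <- function(v) {
  v <- to_matrix3(v)
  if (nrow(v) == 1) return(v)
  Tm <- crossprod(v)
  e <- eigen(Tm, symmetric = TRUE)$vectors[, 1]
  s <- sign(as.numeric(v %*% e))
  s[s == 0] <- 1
  v * s
}

#' @export
print.fisher_stats <- function(x, ...) {
  cat(sprintf(
    "<fisher_stats> n = %d\n  mean %05.1f/%04.1f  R = %.3f  kappa = %.2f\n",
    x$n, x$mean_trend_deg, x$mean_plunge_deg, x$resultant_length_R, x$kappa_hat))
  cat(sprintf("  preferred orientation %.1f%%", x$preferred_orientation_pct))
  if (!is.na(x$alpha95_deg))
    cat(sprintf("  cone of confidence (%.0f%%) %.2f deg",
                100 * (1 - x$significance), x$alpha95_deg))
  cat("\n")
  invisible(x)
}
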