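# Circular statistics for azimuthal (2D) data: vector means and rose-diagram
# binning, in directed (0-360) or axial (0-180, mirrored) mode.

#' Circular vector mean of azimuths
#'
#' Directed mode: the arctangent of the summed unit vectors. Axial mode:
#' angles are doubled, the directed mean of the doubled angles is computed,
#' and halved back, so an axis and its antipode contribute identically.
#'
#' @param azimuth_deg Numeric vector of azimuths, degrees.
#' @param mode `"directed"` or `"axial"`.
#' @return List with `mean_deg` (NA when the resultant vanishes, e.g. for
#'   perfectly antipodal directed data) and `resultant_length` in `[0, 1]`.
#' @export
circular_vector_mean <- function(azimuth_deg, mode = c("directed", "axial")) {
  mode <- match.arg(mode)
  azimuth_deg <- azimuth_deg[!is.na(azimuth_deg)]
  n <- length(azimuth_deg)
  if (n < 1) stop("need at least one azimuth")
  mult <- if (mode == "axial") 2 else 1
  a <- deg2rad(azimuth_deg * mult)
  S <- mean(sin(a)); C <- mean(cos(a))
  rbar <- sqrt(S^2 + C^2)
  if (rbar < 1e-12)
    return(list(mean_deg = NA_real_, resultant_length = rbar))
  m <- rad2deg(atan2(S, C)) / mult
  m <- if (mode == "axial") m %% 180 else m %% 360
  list(mean_deg = m, resultant_length = rbar)
}

#' Rose diagram: binned circular histogram of azimuths
#'
#' Bins are half-open `[lo, hi)` and anchored at 0 degrees. Axial mode folds
#' each azimuth and its antipode together onto `[0, 180)`. The summary carries
#' the circular vector mean, its resultant length, and the maximum class
#' (interval of the most frequent bin and its percentage) -- the class that
#' plots at the circumference under the usual rose-diagram radius convention.
#'
#' @param azimuth_deg Numeric vector of azimuths, degrees; NAs are dropped.
#' @param bin_width_deg Bin width in degrees; must divide 360 (default 20).
#' @param mode `"directed"` or `"axial"`.
#' @return Object of class `rose_diagram`: `bin_edges_deg`, `counts`,
#'   `percentages`, `n`, `vector_mean_deg`, `mean_resultant_length`,
#'   `max_class` (list with `interval_deg`, `percentage`), `mode`,
#'   `bin_width_deg`.
#' @export
rose_histogram <- function(azimuth_deg, bin_width_deg = 20,
                           mode = c("directed", "axial")) {
  mode <- match.arg(mode)
  if (bin_width_deg <= 0 || abs(360 / bin_width_deg - round(360 / bin_width_deg)) > 1e-9)
    stop("bin_width_deg must be a positive divisor of 360")
  azimuth_deg <- azimuth_deg[!is.na(azimuth_deg)]
  stopifnot(all(is.finite(azimuth_deg)))
  span <- if (mode == "axial") 180 else 360
  a <- azimuth_deg %% span
  edges <- seq(0, span, by = bin_width_deg)
  nbins <- length(edges) - 1
  idx <- pmin(nbins, floor(a / bin_width_deg) + 1L)
  counts <- tabulate(idx, nbins)
  n <- length(a)
  pct <- if (n > 0) 100 * counts / n else rep(0, nbins)
  if (n > 0) {
    vm <- circular_vector_mean(azimuth_deg, mode)
    k <- which.max(pct)
    max_class <- list(interval_deg = c(edges[k], edges[k + 1]),
                      percentage = pct[k])
  } else {
    vm <- list(mean_deg = NA_real_, resultant_length = NA_real_)
    max_class <- list(interval_deg = c(NA_real_, NA_real_), percentage = 0)
  }
  structure(list(bin_edges_deg = edges, counts = counts, percentages = pct,
                 n = n, vector_mean_deg = vm$mean_deg,
                 mean_resultant_length = vm$resultant_length,
                 max_class = max_class, mode = mode,
                 bin_width_deg = bin_width_deg),
            class = "rose_diagram")
}

#' @export
print.rose_diagram <- function(x, ...) {
  cat(sprintf("<rose_diagram> %s, %d obs in %d x %g-deg classes\n",
              x$mode, x$n, length(x$counts), x$bin_width_deg))
  if (x$n > 0) {
    cat(sprintf("  vector mean %.1f deg (resultant length %.3f)\n",
                x$vector_mean_deg, x$mean_resultant_length))
    cat(sprintf("  maximum class %.1f%% in [%g, %g)\n",
                x$max_class$percentage, x$max_class$interval_deg[1],
                x$max_class$interval_deg[2]))
  }
  invisible(x)
}
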