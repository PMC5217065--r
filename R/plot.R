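# Base-graphics figures with the field's display conventions: North up,
# azimuths clockwise, and -- for rose diagrams -- the most frequent class
# percentage plotting at the circumference.

#' Plot a rose diagram
#'
#' Circular histogram with sector radius proportional to class percentage,
#' scaled so the maximum class reaches the circumference. The vector mean is
#' drawn as an arrow (directed mode) or a double-ended axis (axial mode).
#'
#' @param x A [rose_histogram()] result.
#' @param show_mean Draw the vector mean.
#' @param main Plot title.
#' @param col Sector fill colour.
#' @param ... Ignored.
#' @export
plot.rose_diagram <- function(x, show_mean = TRUE, main = NULL,
                              col = "steelblue3", ...) {
  op <- graphics::par(mar = c(1, 1, 3, 1), pty = "s")
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(-1.15, 1.15), c(-1.15, 1.15), asp = 1)
  tt <- seq(0, 2 * pi, length.out = 361)
  graphics::lines(sin(tt), cos(tt), col = "grey40")
  for (ring in c(0.25, 0.5, 0.75))
    graphics::lines(ring * sin(tt), ring * cos(tt), col = "grey85", lty = 3)
  graphics::text(0, 1.09, "N"); graphics::text(1.09, 0, "E")
  graphics::text(0, -1.09, "S"); graphics::text(-1.09, 0, "W")
  if (x$n > 0 && x$max_class$percentage > 0) {
    rmax <- x$max_class$percentage
    nb <- length(x$counts)
    reps <- if (x$mode == "axial") c(0, 180) else 0
    for (b in seq_len(nb)) {
      if (x$percentages[b] <= 0) next
      r <- x$percentages[b] / rmax
      for (off in reps) {
        a0 <- deg2rad(x$bin_edges_deg[b] + off)
        a1 <- deg2rad(x$bin_edges_deg[b + 1] + off)
        aa <- seq(a0, a1, length.out = 20)
        graphics::polygon(c(0, r * sin(aa), 0), c(0, r * cos(aa), 0),
                          col = grDevices::adjustcolor(col, 0.7),
                          border = "grey25")
      }
    }
    if (show_mean && !is.na(x$vector_mean_deg)) {
      m <- deg2rad(x$vector_mean_deg)
      graphics::arrows(0, 0, sin(m), cos(m), length = 0.1, lwd = 2, col = "firebrick")
      if (x$mode == "axial")
        graphics::arrows(0, 0, -sin(m), -cos(m), length = 0.1, lwd = 2,
                         col = "firebrick")
    }
  }
  if (is.null(main))
    main <- sprintf("Rose diagram (%s, n = %d), max class %.1f%%",
                    x$mode, x$n, x$max_class$percentage)
  graphics::title(main = main)
  invisible(x)
}

#' Plot lines or plane poles on a lower-hemisphere stereonet
#'
#' @param trend_deg,plunge_deg Lines to plot (e.g. lineations or plane poles).
#' @param method Projection, see [project_lower_hemisphere()].
#' @param planes Optional list of `plane_orientation` objects whose great
#'   circles are traced.
#' @param mean_line Optional length-2 `(trend, plunge)` drawn emphasised, with
#'   `alpha95_deg` (if given) as a small circle around it -- the cone of
#'   confidence.
#' @param alpha95_deg Optional cone half-angle, degrees.
#' @param main Plot title.
#' @param ... Passed to [graphics::points()].
#' @export
plot_stereonet <- function(trend_deg, plunge_deg,
                           method = c("equal_area", "equal_angle"),
                           planes = NULL, mean_line = NULL, alpha95_deg = NULL,
                           main = "Lower-hemisphere stereonet", ...) {
  method <- match.arg(method)
  op <- graphics::par(mar = c(1, 1, 3, 1), pty = "s")
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(-1.15, 1.15), c(-1.15, 1.15), asp = 1)
  tt <- seq(0, 2 * pi, length.out = 361)
  graphics::lines(sin(tt), cos(tt), col = "grey40")
  graphics::segments(c(-0.02, 0), c(0, -0.02), c(0.02, 0), c(0, 0.02),
                     col = "grey40")
  graphics::text(0, 1.09, "N"); graphics::text(1.09, 0, "E")
  graphics::text(0, -1.09, "S"); graphics::text(-1.09, 0, "W")
  if (!is.null(planes))
    for (pl in planes) {
      gc <- plane_to_pole_and_great_circle(pl, method)$great_circle
      graphics::lines(gc$x, gc$y, col = "grey55")
    }
  if (length(trend_deg)) {
    xy <- project_lower_hemisphere(trend_deg, plunge_deg, method)
    graphics::points(xy$x, xy$y, pch = 16, cex = 0.6,
                     col = grDevices::adjustcolor("black", 0.6), ...)
  }
  if (!is.null(mean_line)) {
    mxy <- project_lower_hemisphere(mean_line[1], mean_line[2], method)
    graphics::points(mxy$x, mxy$y, pch = 21, bg = "green3", cex = 1.4)
    if (!is.null(alpha95_deg) && is.finite(alpha95_deg))
      graphics::lines(confidence_small_circle(mean_line, alpha95_deg, method),
                      col = "green4", lwd = 2)
  }
  graphics::title(main = main)
  invisible(NULL)
}

# Projected small circle of half-angle alpha about a mean line: the cone of
# confidence trace. Points on the cone are rotated copies of the mean tilted
# by alpha; upper-hemisphere points are folded axially.
confidence_small_circle <- function(mean_trend_plunge, alpha_deg, method,
                                    n = 181) {
  mu <- as.numeric(trend_plunge_to_cartesian(mean_trend_plunge[1],
                                             mean_trend_plunge[2]))
  Rm <- rotation_to(mu)
  a <- deg2rad(alpha_deg)
  t <- seq(0, 2 * pi, length.out = n)
  local <- cbind(sin(a) * cos(t), sin(a) * sin(t), cos(a))
  v <- local %*% t(Rm)
  tp <- cartesian_to_trend_plunge(v)
  project_lower_hemisphere(tp$trend_deg, tp$plunge_deg, method)
}
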