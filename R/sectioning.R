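# Virtual serial sectioning: slice a scene on parallel planes at a fixed
# grinding interval, reconstruct specimens by cross-section connectivity
# between consecutive slices, place landmarks on the reconstructed outlines,
# and apply the slice-count eligibility rules.
#
# Slices are planes, not slabs: the physical grinding loss is idealised as
# sampling on parallel planes. Slice k sits at z = k * interval from the block
# base (0-based indexing).

#' Slice a scene into a stack of parallel sections
#'
#' Every shell intersecting a slice plane contributes exactly one convex
#' cross-section outline there, computed analytically from the solid shell
#' model (disc or cone) by radial bisection from an interior point -- no
#' rasterisation. The outline vertices lie exactly on the shell surface.
#'
#' @param scene A [generate_scene()] scene.
#' @param interval_mm Slice spacing in mm (default 2, the grinding interval).
#' @param n_outline Vertices per cross-section outline (default 64).
#' @param axis Grinding axis: slice planes are perpendicular to it. `"z"`
#'   stacks horizontal slices through a bed-horizontal frame; `"y"` (the
#'   physical protocol this package emulates) grinds along a horizontal axis,
#'   so sections cut across the bedding and a gently imbricated disc spans
#'   roughly diameter/interval slices.
#' @return Object of class `slice_stack`: `z_positions_mm` (positions along
#'   the grinding axis, length `floor(extent/interval) + 1`), `slices` (per
#'   slice, a list of cross-sections: `source_id`, `taxon`, `z_mm`, `poly`
#'   m x 2 matrix, all in the slicing frame), `interval_mm`, `axis`,
#'   `block_dims_mm`, and `shell_table` (the generating shell table, in the
#'   original frame, retained for validation-mode landmarking only).
#' @export
slice_scene <- function(scene, interval_mm = 2.0, n_outline = 64L,
                        axis = c("z", "y", "x")) {
  stopifnot(inherits(scene, "scene"), n_outline >= 8)
  axis <- match.arg(axis)
  if (interval_mm <= 0) stop("interval_mm must be positive")
  sh_slice <- swap_axis_shells(scene$shells, axis)
  dims_slice <- swap_axis_vec(scene$block_dims_mm, axis)
  height <- dims_slice[3]
  if (interval_mm > height)
    warning("interval exceeds block height; producing a single-slice stack")
  z_positions <- seq(0, height, by = interval_mm)
  slices <- vector("list", length(z_positions))
  sh <- sh_slice
  geoms <- lapply(seq_len(nrow(sh)), function(i) shell_geometry(sh[i, ]))
  for (k in seq_along(z_positions)) {
    z0 <- z_positions[k]
    secs <- list()
    for (i in seq_along(geoms)) {
      g <- geoms[[i]]
      if (z0 <= g$zmin || z0 >= g$zmax) next
      poly <- cross_section_outline(g, z0, n_outline)
      if (is.null(poly)) next
      secs[[length(secs) + 1L]] <- list(source_id = sh$id[i],
                                        taxon = sh$taxon[i],
                                        z_mm = z0, poly = poly)
    }
    slices[[k]] <- secs
  }
  structure(list(z_positions_mm = z_positions, slices = slices,
                 interval_mm = interval_mm, axis = axis,
                 block_dims_mm = scene$block_dims_mm,
                 shell_table = scene$shells),
            class = "slice_stack")
}

# Coordinate swap taking the grinding axis onto the third coordinate; its own
# inverse, so the same swap maps sliced-frame points back.
swap_axis_vec <- function(v, axis) {
  switch(axis, z = v, y = v[c(1, 3, 2)], x = v[c(3, 2, 1)])
}

swap_axis_shells <- function(sh, axis) {
  if (axis == "z" || nrow(sh) == 0) return(sh)
  triples <- list(c("cx", "cy", "cz"), c("pole_x", "pole_y", "pole_z"),
                  c("axis_x", "axis_y", "axis_z"),
                  c("Ax", "Ay", "Az"), c("Bx", "By", "Bz"), c("Cx", "Cy", "Cz"))
  for (cols in triples) {
    swapped <- if (axis == "y") cols[c(1, 3, 2)] else cols[c(3, 2, 1)]
    sh[, cols] <- sh[, swapped]
  }
  sh
}

#' @export
print.slice_stack <- function(x, ...) {
  ncs <- sum(vapply(x$slices, length, integer(1)))
  cat(sprintf("<slice_stack> %d slices at %g mm, %d cross-sections\n",
              length(x$z_positions_mm), x$interval_mm, ncs))
  invisible(x)
}

# Solid geometry of one shell row: a closure bundle with membership test,
# z-range and the points attaining it (used to seed the outline march).
shell_geometry <- function(row) {
  ctr <- as.numeric(row[, c("cx", "cy", "cz")])
  if (row$taxon == "ammonoid") {
    p <- as.numeric(row[, c("pole_x", "pole_y", "pole_z")])
    R <- row$diameter_mm / 2
    th <- row$whorl_width_mm / 2
    sz <- sqrt(max(0, 1 - p[3]^2))     # |horizontal shadow| of the rim
    e <- if (sz > 1e-12) {
      ez <- c(0, 0, 1) - p[3] * p
      ez / sqrt(sum(ez^2))
    } else {
      # horizontal disc: rim contributes no z spread; any in-plane direction
      u <- cross3(p, c(1, 0, 0))
      if (sum(u^2) < 1e-12) u <- cross3(p, c(0, 1, 0))
      u / sqrt(sum(u^2))
    }
    sgn <- if (abs(p[3]) > 1e-12) sign(p[3]) else 1
    pmax_ <- ctr + R * sz * e + th * sgn * p
    pmin_ <- ctr - R * sz * e - th * sgn * p
    list(kind = "disc",
         member = function(pts) {
           rel <- sweep(pts, 2, ctr)
           s <- as.numeric(rel %*% p)
           rad2 <- rowSums(rel^2) - s^2
           abs(s) <= th + 1e-12 & rad2 <= R^2 + 1e-9
         },
         zmin = pmin_[3], zmax = pmax_[3], at_zmin = pmin_, at_zmax = pmax_,
         rho_max = 2 * R + 2 * th)
  } else {
    A <- as.numeric(row[, c("Ax", "Ay", "Az")])   # aperture end (cone base)
    B <- as.numeric(row[, c("Bx", "By", "Bz")])   # apex
    L <- sqrt(sum((A - B)^2))
    q <- (A - B) / L
    rb <- row$whorl_width_mm / 2                  # aperture radius
    sz <- sqrt(max(0, 1 - q[3]^2))
    ring_up <- A[3] + rb * sz
    ring_dn <- A[3] - rb * sz
    ez <- c(0, 0, 1) - q[3] * q
    ez <- if (sum(ez^2) > 1e-24) ez / sqrt(sum(ez^2)) else {
      u <- cross3(q, c(1, 0, 0)); u / sqrt(sum(u^2))
    }
    if (B[3] >= ring_up) { zmax <- B[3]; at_zmax <- B }
    else { zmax <- ring_up; at_zmax <- A + rb * ez }
    if (B[3] <= ring_dn) { zmin <- B[3]; at_zmin <- B }
    else { zmin <- ring_dn; at_zmin <- A - rb * ez }
    list(kind = "cone",
         member = function(pts) {
           rel <- sweep(pts, 2, B)
           s <- as.numeric(rel %*% q)
           rad2 <- rowSums(rel^2) - s^2
           s >= -1e-12 & s <= L + 1e-12 & rad2 <= (rb * s / L)^2 + 1e-9
         },
         zmin = zmin, zmax = zmax, at_zmin = at_zmin, at_zmax = at_zmax,
         rho_max = L + 2 * rb)
  }
}

# Convex cross-section outline of a solid at plane z = z0: an interior point
# is taken on the segment joining the solid's z-extreme points (inside by
# convexity), then the boundary is found by radial bisection in n directions.
cross_section_outline <- function(g, z0, n_dirs = 64L, iters = 40L) {
  lam <- (z0 - g$zmin) / (g$zmax - g$zmin)
  p0 <- g$at_zmin + lam * (g$at_zmax - g$at_zmin)
  theta <- seq(0, 2 * pi, length.out = n_dirs + 1L)[-(n_dirs + 1L)]
  dx <- cos(theta); dy <- sin(theta)
  lo <- numeric(n_dirs)
  hi <- rep(g$rho_max, n_dirs)
  for (it in seq_len(iters)) {
    mid <- (lo + hi) / 2
    pts <- cbind(p0[1] + mid * dx, p0[2] + mid * dy, z0)
    inside <- g$member(pts)
    lo[inside] <- mid[inside]
    hi[!inside] <- mid[!inside]
  }
  if (all(lo < 1e-9)) return(NULL)   # tangential graze
  cbind(x = p0[1] + lo * dx, y = p0[2] + lo * dy)
}

#' Reconstruct specimens from a slice stack
#'
#' Cross-sections are grouped into specimens by 2D overlap of their outlines
#' between consecutive slices. An outline joins the outline in the previous
#' slice with which it shares the largest positive overlap area (ties broken
#' toward the lowest index). Where no outline overlaps, a proximity fallback
#' joins it to the nearest previous-slice outline within `connect_tol_mm`:
#' a shell thinner than the slice interval, or an inclined cone near its
#' apex, legitimately produces consecutive sections with a small plan-view
#' gap, which the human segmentation this step emulates would still join.
#' Groups are the connected components of those links. Source shell ids are
#' retained on each specimen so grouping accuracy is measurable against
#' ground truth.
#'
#' @param stack A [slice_scene()] stack.
#' @param connect_tol_mm Maximum plan-view gap joined by the proximity
#'   fallback; defaults to twice the slice interval (an inclined feature
#'   shifts laterally by interval/tan(plunge) per slice, so a one-interval
#'   tolerance is too tight for moderately plunging cones).
#' @return List of `reconstructed_specimen` objects: `id`, `taxon`,
#'   `slice_count`, `sections` (member cross-sections), `source_ids`.
#' @export
reconstruct_specimens <- function(stack, connect_tol_mm = NULL) {
  stopifnot(inherits(stack, "slice_stack"))
  if (is.null(connect_tol_mm)) connect_tol_mm <- 2 * stack$interval_mm
  flat <- list(); slice_of <- integer(0)
  for (k in seq_along(stack$slices)) {
    for (cs in stack$slices[[k]]) {
      flat[[length(flat) + 1L]] <- cs
      slice_of <- c(slice_of, k)
    }
  }
  m <- length(flat)
  if (m == 0) return(list())
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }

  bboxes <- t(vapply(flat, function(cs)
    c(range(cs$poly[, 1]), range(cs$poly[, 2])), numeric(4)))
  tol <- connect_tol_mm
  for (k in seq_along(stack$slices)[-1]) {
    cur <- which(slice_of == k)
    prev <- which(slice_of == k - 1L)
    if (!length(cur) || !length(prev)) next
    for (i in cur) {
      best_j <- 0L; best_area <- 0
      near_j <- 0L; near_gap <- Inf
      for (j in prev) {
        if (bboxes[i, 1] > bboxes[j, 2] + tol || bboxes[j, 1] > bboxes[i, 2] + tol ||
            bboxes[i, 3] > bboxes[j, 4] + tol || bboxes[j, 3] > bboxes[i, 4] + tol)
          next
        a <- convex_overlap_area(flat[[i]]$poly, flat[[j]]$poly)
        if (a > best_area + 1e-12 ||
            (a > 0 && abs(a - best_area) <= 1e-12 && j < best_j)) {
          best_area <- a; best_j <- j
        }
        if (a <= 0) {
          g <- min_vertex_gap(flat[[i]]$poly, flat[[j]]$poly)
          if (g < near_gap - 1e-12) { near_gap <- g; near_j <- j }
        }
      }
      if (best_j > 0L && best_area > 0) unite(i, best_j)
      else if (near_j > 0L && near_gap <= tol) unite(i, near_j)
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  comp_ids <- sort(unique(roots))
  out <- vector("list", length(comp_ids))
  for (ci in seq_along(comp_ids)) {
    members <- which(roots == comp_ids[ci])
    secs <- flat[members]
    taxa <- vapply(secs, function(s) s$taxon, character(1))
    out[[ci]] <- structure(list(
      id = ci,
      taxon = names(sort(table(taxa), decreasing = TRUE))[1],
      slice_count = length(unique(slice_of[members])),
      sections = secs,
      axis = stack$axis %||% "z",
      source_ids = sort(unique(vapply(secs, function(s) s$source_id, numeric(1))))),
      class = "reconstructed_specimen")
  }
  out
}

#' @export
print.reconstructed_specimen <- function(x, ...) {
  cat(sprintf("<reconstructed_specimen> #%d (%s), %d slices, %d sections\n",
              x$id, x$taxon, x$slice_count, length(x$sections)))
  invisible(x)
}

#' Extract landmarks from a reconstructed specimen
#'
#' A is the aperture-most point of the reconstructed outline union; with a
#' ground-truth aperture marker available (validation mode) it is the outline
#' vertex closest to the marker, otherwise (blind mode) the vertex farthest
#' from the outline centroid -- a documented best-effort heuristic. B is the
#' vertex maximising distance from A, and C (ammonoids) the vertex maximising
#' distance from the line A-B. C is dropped, with a degeneracy flag, when the
#' reconstruction is collinear.
#'
#' For ammonoids the selected points are then projected onto the
#' total-least-squares plane of the whole outline cloud. Outline vertices sit
#' on the shell's outer surface, up to half a whorl width off the sagittal
#' mid-plane; the projection emulates the operator's placement of landmarks
#' on the sagittal plane itself and removes that tube-width bias from the
#' A-B-C plane.
#'
#' @param spec A `reconstructed_specimen`.
#' @param aperture_marker Optional length-3 true aperture point (mm).
#' @param snap_sagittal Project ammonoid landmarks onto the fitted sagittal
#'   plane (default TRUE). With FALSE the raw outline vertices are returned:
#'   they lie exactly on the reconstructed shell surface and converge to the
#'   true margin points as the slice interval shrinks, but carry the
#'   tube-width offset in the A-B-C plane.
#' @return A [landmark_set()] with attribute `degenerate_plane` when C could
#'   not be placed for an ammonoid.
#' @export
extract_landmarks <- function(spec, aperture_marker = NULL,
                              snap_sagittal = TRUE) {
  stopifnot(inherits(spec, "reconstructed_specimen"))
  if (spec$slice_count < 2) stop("specimen needs at least 2 slices for landmarks")
  axis <- spec$axis %||% "z"
  if (!is.null(aperture_marker))
    aperture_marker <- swap_axis_vec(as.numeric(aperture_marker), axis)
  # uniform arc-length resampling per outline, with per-vertex weights
  # proportional to the arc length each represents: together these make the
  # vertex cloud approximate a uniform sampling of the shell surface. The
  # radial march spaces vertices by angle about its interior seed, and every
  # cut carries the same vertex count however short its boundary, so the raw
  # cloud over-represents sliver cuts near the z-extremes and would bias the
  # total-least-squares plane below.
  pieces <- lapply(spec$sections, function(s) {
    p <- resample_polygon(s$poly, nrow(s$poly))
    list(pts = cbind(p[, 1], p[, 2], s$z_mm),
         w = rep(polygon_perimeter(p) / nrow(p), nrow(p)))
  })
  pts <- do.call(rbind, lapply(pieces, `[[`, "pts"))
  wts <- unlist(lapply(pieces, `[[`, "w"))
  if (!is.null(aperture_marker)) {
    d2 <- rowSums(sweep(pts, 2, as.numeric(aperture_marker))^2)
    A <- pts[which.min(d2), ]
  } else {
    ctrd <- colMeans(pts)
    A <- pts[which.max(rowSums(sweep(pts, 2, ctrd)^2)), ]
  }
  dB <- rowSums(sweep(pts, 2, A)^2)
  B <- pts[which.max(dB), ]
  C <- NULL
  degenerate <- FALSE
  if (spec$taxon == "ammonoid") {
    ab <- B - A
    ab <- ab / sqrt(sum(ab^2))
    rel <- sweep(pts, 2, A)
    proj <- as.numeric(rel %*% ab)
    off2 <- rowSums(rel^2) - proj^2
    k <- which.max(off2)
    if (off2[k] > (2 * AREA_TOL)^2) C <- pts[k, ] else degenerate <- TRUE
    if (snap_sagittal && !degenerate && nrow(pts) >= 8) {
      fit <- tls_plane(pts, wts)
      snap <- function(p) p - sum((p - fit$centroid) * fit$normal) * fit$normal
      A2 <- snap(A); B2 <- snap(B); C2 <- snap(C)
      # keep the snap only while it stays a valid, non-collinear triangle
      if (sqrt(sum((A2 - B2)^2)) > LENGTH_TOL &&
          triangle_area(A2, B2, C2) > AREA_TOL) {
        A <- A2; B <- B2; C <- C2
      }
    }
  }
  lm <- landmark_set(swap_axis_vec(A, axis), swap_axis_vec(B, axis),
                     if (is.null(C)) NULL else swap_axis_vec(C, axis))
  attr(lm, "degenerate_plane") <- degenerate
  lm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Weighted total-least-squares plane of a point cloud: weighted centroid plus
# the singular vector of the smallest singular value of the sqrt-weighted
# centred cloud.
tls_plane <- function(pts, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(pts))
  ctr <- colSums(pts * w) / sum(w)
  sv <- svd(sweep(pts, 2, ctr) * sqrt(w))
  list(centroid = ctr, normal = sv$v[, 3])
}

polygon_perimeter <- function(p) {
  closed <- rbind(p, p[1, , drop = FALSE])
  sum(sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2))
}

#' Landmark table for a list of reconstructed specimens
#'
#' Runs [extract_landmarks()] on every specimen with at least two slices,
#' using the stack's retained shell table as aperture markers (validation
#' mode) unless `blind = TRUE`.
#'
#' @param specimens List from [reconstruct_specimens()].
#' @param stack The originating [slice_scene()] stack (for markers).
#' @param blind Ignore ground-truth aperture markers.
#' @return Data frame with columns `specimen_id`, `taxon`, `Ax..Cz`,
#'   `slice_count` (the landmark CSV schema).
#' @export
landmark_table <- function(specimens, stack = NULL, blind = FALSE) {
  keep <- Filter(function(s) s$slice_count >= 2, specimens)
  n <- length(keep)
  out <- data.frame(specimen_id = integer(n), taxon = character(n),
                    Ax = numeric(n), Ay = numeric(n), Az = numeric(n),
                    Bx = numeric(n), By = numeric(n), Bz = numeric(n),
                    Cx = NA_real_, Cy = NA_real_, Cz = NA_real_,
                    slice_count = integer(n), stringsAsFactors = FALSE)
  if (n == 0) return(out[0, ])
  for (i in seq_len(n)) {
    sp <- keep[[i]]
    marker <- NULL
    if (!blind && !is.null(stack) && length(sp$source_ids) >= 1) {
      row <- stack$shell_table[match(sp$source_ids[1], stack$shell_table$id), ]
      marker <- as.numeric(row[, c("Ax", "Ay", "Az")])
    }
    lm <- extract_landmarks(sp, aperture_marker = marker)
    out$specimen_id[i] <- sp$id
    out$taxon[i] <- sp$taxon
    out[i, c("Ax", "Ay", "Az")] <- lm$A
    out[i, c("Bx", "By", "Bz")] <- lm$B
    if (!is.null(lm$C)) out[i, c("Cx", "Cy", "Cz")] <- lm$C
    out$slice_count[i] <- sp$slice_count
  }
  out
}

#' Partition specimens by slice-count eligibility
#'
#' Ammonoids reconstructed from at least `lineation` slices (default 6) enter
#' the lineation A:B analysis; at least `plane` slices (default 3) the
#' sagittal-plane analysis; gastropods intersected at least `gastropod` times
#' (default 2) enter the gastropod lineation analysis. Every specimen remains
#' in the total count regardless of eligibility.
#'
#' @param specimens List of `reconstructed_specimen` (or a data frame with
#'   `taxon` and `slice_count` columns).
#' @param thresholds Named list with `lineation`, `plane`, `gastropod`.
#' @return List of integer index vectors: `lineation_eligible`,
#'   `plane_eligible`, `gastropod_eligible`, `counted_only`, plus `n_total`.
#' @export
eligibility_filter <- function(specimens,
                               thresholds = list(lineation = 6L, plane = 3L,
                                                 gastropod = 2L)) {
  if (is.data.frame(specimens)) {
    taxon <- specimens$taxon
    sc <- specimens$slice_count
  } else {
    taxon <- vapply(specimens, function(s) s$taxon, character(1))
    sc <- vapply(specimens, function(s) s$slice_count, numeric(1))
  }
  amm <- taxon == "ammonoid"
  lin <- which(amm & sc >= thresholds$lineation)
  pla <- which(amm & sc >= thresholds$plane)
  gas <- which(!amm & sc >= thresholds$gastropod)
  rest <- setdiff(seq_along(taxon), union(union(lin, pla), gas))
  list(lineation_eligible = lin, plane_eligible = pla,
       gastropod_eligible = gas, counted_only = rest,
       n_total = length(taxon))
}

# Resample a closed polygon to n vertices at uniform arc-length spacing.
resample_polygon <- function(poly, n) {
  m <- nrow(poly)
  if (m < 3) return(poly)
  closed <- rbind(poly, poly[1, , drop = FALSE])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  cum <- c(0, cumsum(seg))
  per <- cum[m + 1]
  if (per < 1e-12) return(poly)
  target <- seq(0, per, length.out = n + 1L)[-(n + 1L)]
  idx <- findInterval(target, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, m)
  frac <- (target - cum[idx]) / pmax(seg[idx], 1e-300)
  cbind(x = closed[idx, 1] + frac * (closed[idx + 1L, 1] - closed[idx, 1]),
        y = closed[idx, 2] + frac * (closed[idx + 1L, 2] - closed[idx, 2]))
}

# Smallest distance between the vertex sets of two (densely sampled) convex
# outlines; a cheap proxy for polygon-polygon distance at the vertex spacing
# of the outlines.
min_vertex_gap <- function(p, q) {
  d2 <- outer(rowSums(p^2), rowSums(q^2), "+") - 2 * tcrossprod(p, q)
  sqrt(max(0, min(d2)))
}

# ---- convex polygon overlap (Sutherland-Hodgman) --------------------------

# Area of the intersection of two convex polygons (counter-clockwise or
# clockwise vertex order both accepted; orientation is normalised first).
convex_overlap_area <- function(p, q) {
  p <- ccw(p); q <- ccw(q)
  clipped <- p
  nq <- nrow(q)
  for (e in seq_len(nq)) {
    if (nrow(clipped) == 0) return(0)
    a <- q[e, ]; b <- q[if (e == nq) 1L else e + 1L, ]
    clipped <- clip_halfplane(clipped, a, b)
  }
  polygon_area(clipped)
}

ccw <- function(p) if (polygon_signed_area(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p

polygon_signed_area <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  j <- c(2:n, 1L)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

polygon_area <- function(p) abs(polygon_signed_area(p))

# Keep the part of convex polygon `poly` on the left of directed edge a->b.
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  ex <- b[1] - a[1]; ey <- b[2] - a[2]
  # cross((b - a), (p - a)) >= 0 means p lies left of the edge, i.e. inside
  side <- ex * (poly[, 2] - a[2]) - ey * (poly[, 1] - a[1])
  inside <- side >= -1e-12
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_ <- poly[i, ]; pj <- poly[j, ]
    si <- side[i]; sj <- side[j]
    if (si >= -1e-12) out <- rbind(out, pi_)
    if ((si >= -1e-12) != (sj >= -1e-12)) {
      t <- si / (si - sj)
      out <- rbind(out, pi_ + t * (pj - pi_))
    }
  }
  out
}
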