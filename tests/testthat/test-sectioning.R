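# Virtual sectioning: slicing, specimen reconstruction, landmark placement,
# eligibility rules.

shift_shell_z <- function(scene, new_cz) {
  dz <- new_cz - scene$shells$cz[1]
  for (col in c("cz", "Az", "Bz", "Cz"))
    scene$shells[[col]] <- scene$shells[[col]] + dz
  scene
}

test_that("slice count follows floor(height/interval) + 1", {
  cfg <- fabric_config(n_ammonoids = 1L, n_gastropods = 0L)
  sc <- generate_scene(cfg, block_dims_mm = c(150, 45, 140), seed = 1)
  st <- slice_scene(sc, 2)
  expect_length(st$z_positions_mm, 71)
  expect_equal(diff(st$z_positions_mm), rep(2, 70))
  expect_warning(slice_scene(sc, 200), "single-slice")
})

test_that("a thin horizontal disc lying between planes yields no cross-section", {
  sc <- single_ammonoid_scene(diameter = 6, pole_trend = 0, pole_plunge = 90,
                              block = c(60, 60, 60))
  # whorl width 1.5 mm: z-extent 3 +/- 0.75, strictly between planes 2 and 4
  sc <- shift_shell_z(sc, 3)
  st <- slice_scene(sc, 2)
  expect_equal(sum(vapply(st$slices, length, integer(1))), 0)
  expect_length(reconstruct_specimens(st), 0)
})

test_that("the slice span of a disc matches the analytic z-extent", {
  # vertical disc (pole horizontal), diameter 27.7, centred on a plane
  sc <- single_ammonoid_scene(diameter = 27.7, pole_trend = 40, pole_plunge = 0,
                              block = c(140, 140, 140))
  sc <- shift_shell_z(sc, 70)
  st <- slice_scene(sc, 2)
  hit <- which(vapply(st$slices, length, integer(1)) > 0)
  expect_equal(length(hit), sum(st$z_positions_mm > 70 - 27.7 / 2 &
                                  st$z_positions_mm < 70 + 27.7 / 2))

  # generic case: span = diameter * sqrt(1 - pole_z^2) + whorl * |pole_z|
  sc <- single_ammonoid_scene(diameter = 20, pole_trend = 335, pole_plunge = 76,
                              block = c(140, 140, 140))
  sc <- shift_shell_z(sc, 71)   # off-grid centre
  st <- slice_scene(sc, 2)
  hit <- which(vapply(st$slices, length, integer(1)) > 0)
  pz <- abs(sc$shells$pole_z[1])
  half_span <- 10 * sqrt(1 - pz^2) + (20 / 4 / 2) * pz
  expect_equal(length(hit), sum(st$z_positions_mm > 71 - half_span &
                                  st$z_positions_mm < 71 + half_span))
})

test_that("reconstruction separates shells and conserves cross-sections", {
  # one shell, one specimen
  sc <- single_ammonoid_scene(diameter = 20)
  st <- slice_scene(sc, 2)
  sp <- reconstruct_specimens(st)
  expect_length(sp, 1)
  expect_equal(sp[[1]]$source_ids, 1)

  # two well-separated shells, two specimens
  cfg <- fabric_config(n_ammonoids = 2L, n_gastropods = 0L, pole_kappa = 1e9,
                       packing = "matrix_supported", min_spacing_mm = 70)
  sc <- generate_scene(cfg, block_dims_mm = c(200, 200, 100), seed = 8)
  st <- slice_scene(sc, 2)
  sp <- reconstruct_specimens(st)
  expect_length(sp, 2)
  expect_true(all(lengths(lapply(sp, `[[`, "source_ids")) == 1))

  # conservation: every cross-section belongs to exactly one specimen
  n_cs <- sum(vapply(st$slices, length, integer(1)))
  expect_equal(sum(vapply(sp, function(s) length(s$sections), integer(1))), n_cs)
})

test_that("grouping on a sparse non-overlapping scene matches ground truth ids", {
  cfg <- fabric_config(n_ammonoids = 90L, n_gastropods = 10L, pole_kappa = 30,
                       packing = "matrix_supported", min_spacing_mm = 28)
  sc <- generate_scene(cfg, block_dims_mm = c(300, 300, 140), seed = 9)
  st <- slice_scene(sc, 2)
  sp <- reconstruct_specimens(st)
  ids_in_stack <- sort(unique(unlist(lapply(st$slices, function(sl)
    vapply(sl, function(cs) cs$source_id, numeric(1))))))
  # one specimen per sectioned shell, each with a single source id
  expect_length(sp, length(ids_in_stack))
  expect_true(all(lengths(lapply(sp, `[[`, "source_ids")) == 1))
  expect_equal(sort(unlist(lapply(sp, `[[`, "source_ids"))), ids_in_stack)
  expect_lte(length(sp), nrow(sc$shells))
})

test_that("landmarks on an analytically exact rim recover the diameter", {
  R <- 10
  phi <- seq(0, 2 * pi, length.out = 65)[-65]   # even count: antipodal pairs
  rim <- cbind(x = 30 + R * cos(phi), y = 30 + R * sin(phi))
  spec <- structure(list(id = 1L, taxon = "ammonoid", slice_count = 2L,
                         sections = list(list(source_id = 1, taxon = "ammonoid",
                                              z_mm = 10, poly = rim)),
                         source_ids = 1),
                    class = "reconstructed_specimen")
  lm <- extract_landmarks(spec)
  expect_equal(sqrt(sum((lm$A - lm$B)^2)), 2 * R, tolerance = 1e-9)
  # a full rim is planar but not collinear: C must be present
  expect_false(is.null(lm$C))
})

test_that("reconstructed landmarks track ground truth within the slice interval", {
  sc <- single_ammonoid_scene(diameter = 20, pole_trend = 335, pole_plunge = 76,
                              block = c(80, 80, 80))
  st <- slice_scene(sc, 2)
  sp <- reconstruct_specimens(st)
  expect_length(sp, 1)
  lt <- landmark_table(sp, st)
  o <- measure_orientations(lt)
  expect_equal(o$max_diameter_mm, 20, tolerance = 2)
  A_true <- as.numeric(sc$shells[1, c("Ax", "Ay", "Az")])
  A_est <- as.numeric(lt[1, c("Ax", "Ay", "Az")])
  expect_lte(abs(A_est[3] - A_true[3]), 2)        # z error within one interval
  # per-shell plane error is discretization-limited: ~atan(interval/(D/2))
  # at 3 slices through a 20 mm disc; the fabric MEAN is unbiased (see the
  # end-to-end recovery test)
  expect_lt(axial_angle_deg(o$pole_trend_deg, o$pole_plunge_deg, 335, 76), 12)
})

test_that("landmark error vanishes as the slice interval shrinks", {
  sc <- single_ammonoid_scene(diameter = 20, pole_trend = 335, pole_plunge = 76,
                              block = c(80, 80, 80))
  A_true <- as.numeric(sc$shells[1, c("Ax", "Ay", "Az")])
  # raw surface landmarks (snap_sagittal = FALSE) converge to the true
  # margin points; fine angular sampling so the outline vertex spacing does
  # not floor the error before the slice interval does
  err <- vapply(c(2.0, 0.5, 0.1), function(h) {
    sp <- reconstruct_specimens(slice_scene(sc, h, n_outline = 256L))
    lm <- extract_landmarks(sp[[1]], aperture_marker = A_true,
                            snap_sagittal = FALSE)
    sqrt(sum((lm$A - A_true)^2))
  }, numeric(1))
  expect_lt(err[3], err[1] + 1e-9)
  expect_lt(err[3], 0.3)
  expect_lt(err[2], 2)
})

test_that("gastropod cones land A at the aperture and B at the apex", {
  sc <- single_gastropod_scene(length_mm = 9, axis_trend = 153, axis_plunge = 24,
                               block = c(60, 60, 60))
  st <- slice_scene(sc, 0.5)
  sp <- reconstruct_specimens(st)
  expect_length(sp, 1)
  lt <- landmark_table(sp, st)
  expect_equal(lt$taxon, "gastropod")
  L <- sqrt(sum((as.numeric(lt[1, c("Ax", "Ay", "Az")]) -
                   as.numeric(lt[1, c("Bx", "By", "Bz")]))^2))
  expect_equal(L, 9, tolerance = 1)
  A_true <- as.numeric(sc$shells[1, c("Ax", "Ay", "Az")])
  B_true <- as.numeric(sc$shells[1, c("Bx", "By", "Bz")])
  expect_lt(sqrt(sum((as.numeric(lt[1, c("Ax", "Ay", "Az")]) - A_true)^2)), 2.5)
  expect_lt(sqrt(sum((as.numeric(lt[1, c("Bx", "By", "Bz")]) - B_true)^2)), 2.5)
  # no C for two-landmark specimens
  expect_true(is.na(lt$Cx))
})

test_that("eligibility thresholds partition specimens as the slice rules demand", {
  tab <- data.frame(taxon = c(rep("ammonoid", 5), "gastropod", "gastropod"),
                    slice_count = c(2, 3, 5, 6, 9, 1, 2))
  part <- eligibility_filter(tab)
  # brute-force enumeration of the spans
  amm <- tab$slice_count[tab$taxon == "ammonoid"]
  expect_length(part$lineation_eligible, sum(amm >= 6))   # = 2
  expect_length(part$plane_eligible, sum(amm >= 3))       # = 4
  expect_equal(part$lineation_eligible, c(4L, 5L))
  expect_equal(part$plane_eligible, c(2L, 3L, 4L, 5L))
  expect_equal(part$gastropod_eligible, 7L)
  expect_equal(part$n_total, 7)
  # an ammonoid at exactly 6 slices is eligible for both analyses
  one <- eligibility_filter(data.frame(taxon = "ammonoid", slice_count = 6))
  expect_equal(one$lineation_eligible, 1L)
  expect_equal(one$plane_eligible, 1L)
  # at exactly 3 slices, the sagittal-plane analysis only
  one <- eligibility_filter(data.frame(taxon = "ammonoid", slice_count = 3))
  expect_length(one$lineation_eligible, 0)
  expect_equal(one$plane_eligible, 1L)
})

test_that("extracted azimuths rotate with the scene", {
  rot_scene_z <- function(scene, theta_deg, c0) {
    a <- theta_deg * pi / 180
    rot <- function(x, y) list(x = cos(a) * (x - c0[1]) + sin(a) * (y - c0[2]) + c0[1],
                               y = -sin(a) * (x - c0[1]) + cos(a) * (y - c0[2]) + c0[2])
    sh <- scene$shells
    for (pair in list(c("cx", "cy"), c("Ax", "Ay"), c("Bx", "By"),
                      c("Cx", "Cy"))) {
      r <- rot(sh[[pair[1]]], sh[[pair[2]]])
      sh[[pair[1]]] <- r$x; sh[[pair[2]]] <- r$y
    }
    rv <- rot(sh$pole_x + c0[1], sh$pole_y + c0[2])
    sh$pole_x <- rv$x - c0[1]; sh$pole_y <- rv$y - c0[2]
    scene$shells <- sh
    scene
  }
  for (seed in 1:4) {
    sc <- single_ammonoid_scene(diameter = 18, pole_trend = 335, pole_plunge = 70,
                                seed = seed, block = c(90, 90, 60))
    theta <- c(35, 110, 260, 300)[seed]
    sc_r <- rot_scene_z(sc, theta, c0 = c(45, 45, 0))
    o0 <- {
      st <- slice_scene(sc, 2, n_outline = 192L)
      measure_orientations(landmark_table(reconstruct_specimens(st), st))
    }
    o1 <- {
      st <- slice_scene(sc_r, 2, n_outline = 192L)
      measure_orientations(landmark_table(reconstruct_specimens(st), st))
    }
    d_ap <- abs((o0$aperture_azimuth_deg + theta - o1$aperture_azimuth_deg) %% 360)
    expect_lt(min(d_ap, 360 - d_ap), 2)
    d_dd <- abs((o0$dip_direction_deg + theta - o1$dip_direction_deg) %% 360)
    expect_lt(min(d_dd, 360 - d_dd), 2)
    expect_equal(o0$dip_deg, o1$dip_deg, tolerance = 2)
  }
})
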