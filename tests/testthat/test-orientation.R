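# Landmark-to-orientation geometry: lineation A:B, sagittal plane A-B-C,
# and the stratigraphic overturn correction.

test_that("lineation from landmarks handles axis-aligned, vertical and generic cases", {
  # horizontal axis pointing North: aperture due North
  ln <- lineation_from_landmarks(landmark_set(A = c(0, 10, 0), B = c(0, 0, 0)))
  expect_equal(ln$plunge_deg, 0)
  expect_equal(ln$directed_azimuth_deg, 0)
  expect_equal(ln$max_diameter_mm, 10)
  expect_equal(ln$trend_deg, 0)  # horizontal trend normalised into [0, 180)

  # vertical axis: plunge 90, trend normalised, aperture azimuth undefined
  ln <- lineation_from_landmarks(landmark_set(A = c(0, 0, 0), B = c(0, 0, 10)))
  expect_equal(ln$plunge_deg, 90)
  expect_equal(ln$trend_deg, 0)
  expect_true(is.na(ln$directed_azimuth_deg))

  # round trip through the inverse construction at the reference fabric 144/18
  v <- as.numeric(trend_plunge_to_cartesian(144, 18))
  A <- c(3, -2, 1)
  ln <- lineation_from_landmarks(landmark_set(A = A, B = A + 12 * v))
  expect_equal(ln$trend_deg, 144, tolerance = 1e-9)
  expect_equal(ln$plunge_deg, 18, tolerance = 1e-9)
  expect_equal(ln$max_diameter_mm, 12, tolerance = 1e-12)
  # A - B = -12 v: the aperture sits at the shallow (upper) end
  expect_equal(ln$directed_azimuth_deg, (144 + 180) %% 360, tolerance = 1e-9)
})

test_that("degenerate landmark sets are rejected", {
  expect_error(landmark_set(A = c(0, 0, 0), B = c(0, 0, 1e-9)), "degenerate")
  expect_error(landmark_set(A = c(0, 0, 0), B = c(10, 0, 0), C = c(5, 0, 0)),
               "collinear")
})

test_that("plane from landmarks matches trivial constructions", {
  pl <- plane_from_landmarks(landmark_set(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)))
  expect_equal(pl$dip_deg, 0)

  # vertical N-S plane: dip 90, tie broken into [0, 180) so dip direction 90
  pl <- plane_from_landmarks(landmark_set(c(0, 0, 0), c(0, 10, 0), c(0, 0, 10)))
  expect_equal(pl$dip_deg, 90)
  expect_equal(pl$dip_direction_deg, 90)

  # inverse construction at the reference fabric: dip 14 toward 155
  lm <- plane_landmarks(14, 155)
  pl <- plane_from_landmarks(landmark_set(lm$A, lm$B, lm$C))
  expect_equal(pl$dip_deg, 14, tolerance = 1e-9)
  expect_equal(pl$dip_direction_deg, 155, tolerance = 1e-9)
})

test_that("plane dip/dip-direction matches the SVD oracle on random triples", {
  set.seed(11)
  for (i in 1:300) {
    A <- stats::rnorm(3, sd = 5)
    B <- A + stats::rnorm(3, sd = 5)
    C <- A + stats::rnorm(3, sd = 5)
    lm <- tryCatch(landmark_set(A, B, C), error = function(e) NULL)
    if (is.null(lm)) next
    pl <- plane_from_landmarks(lm)
    ora <- oracle_dip_dipdir(A, B, C)
    expect_equal(pl$dip_deg, unname(ora["dip"]), tolerance = 1e-9)
    expect_equal(pl$dip_direction_deg, unname(ora["dip_direction"]),
                 tolerance = 1e-9)
    # pole/plane consistency invariant, exact by construction
    expect_equal(pl$pole$trend_deg, (pl$dip_direction_deg + 180) %% 360)
    expect_equal(pl$pole$plunge_deg, 90 - pl$dip_deg)
  }
})

test_that("orientations are frame-equivariant and scale-invariant", {
  set.seed(21)
  rotz <- function(x, th) {
    a <- th * pi / 180
    R <- matrix(c(cos(a), sin(a), 0,
                  -sin(a), cos(a), 0,
                  0, 0, 1), 3, 3, byrow = TRUE)
    as.numeric(R %*% x)  # adds th to every azimuth (clockwise-from-North frame)
  }
  for (i in 1:50) {
    A <- stats::rnorm(3, sd = 5); B <- A + stats::rnorm(3, sd = 5)
    C <- A + stats::rnorm(3, sd = 5)
    th <- stats::runif(1, 0, 360)
    k <- stats::runif(1, 0.1, 20)
    lm0 <- landmark_set(A, B, C)
    lmr <- landmark_set(rotz(A, th), rotz(B, th), rotz(C, th))
    lms <- landmark_set(k * A, k * B, k * C)
    l0 <- lineation_from_landmarks(lm0); lr <- lineation_from_landmarks(lmr)
    p0 <- plane_from_landmarks(lm0); pr <- plane_from_landmarks(lmr)
    if (l0$plunge_deg > 1e-6 && l0$plunge_deg < 90 - 1e-6) {
      expect_equal((l0$trend_deg + th) %% 360, lr$trend_deg %% 360,
                   tolerance = 1e-9)
      expect_equal((l0$directed_azimuth_deg + th) %% 360,
                   lr$directed_azimuth_deg, tolerance = 1e-9)
    }
    expect_equal(l0$plunge_deg, lr$plunge_deg, tolerance = 1e-9)
    if (p0$dip_deg > 1e-6 && p0$dip_deg < 90 - 1e-6)
      expect_equal((p0$dip_direction_deg + th) %% 360, pr$dip_direction_deg,
                   tolerance = 1e-9)
    expect_equal(p0$dip_deg, pr$dip_deg, tolerance = 1e-9)
    # scaling leaves all angles unchanged; |A-B| scales linearly
    ls <- lineation_from_landmarks(lms); ps <- plane_from_landmarks(lms)
    expect_equal(ls$trend_deg, l0$trend_deg, tolerance = 1e-9)
    expect_equal(ls$plunge_deg, l0$plunge_deg, tolerance = 1e-9)
    expect_equal(ps$dip_deg, p0$dip_deg, tolerance = 1e-9)
    expect_equal(ls$max_diameter_mm, k * l0$max_diameter_mm, tolerance = 1e-9)
  }
})

test_that("overturn correction agrees with the rotation-matrix oracle", {
  set.seed(31)
  for (i in 1:100) {
    axis <- stats::runif(1, 0, 360)
    tp <- random_lines(1)
    R <- oracle_rotation_matrix(axis, pi)
    v <- as.numeric(trend_plunge_to_cartesian(tp$trend_deg, tp$plunge_deg))
    expect_tp <- cartesian_to_trend_plunge(as.numeric(R %*% v))
    got <- correct_overturn(line_orientation(tp$trend_deg, tp$plunge_deg), axis)
    expect_equal(got$trend_deg, expect_tp$trend_deg, tolerance = 1e-9)
    expect_equal(got$plunge_deg, expect_tp$plunge_deg, tolerance = 1e-9)

    pl <- plane_orientation(stats::runif(1, 0, 89), stats::runif(1, 0, 360))
    pv <- as.numeric(trend_plunge_to_cartesian(pl$pole$trend_deg,
                                               pl$pole$plunge_deg))
    ora <- coquina:::plane_from_normal(as.numeric(R %*% pv))
    got <- correct_overturn(pl, axis)
    expect_equal(got$dip_deg, ora$dip_deg, tolerance = 1e-9)
    expect_equal(got$dip_direction_deg, ora$dip_direction_deg, tolerance = 1e-9)
  }
})

test_that("overturn correction is an involution and fixes perpendicular planes", {
  # the pole of a plane dipping toward 155 is perpendicular to the 065 axis:
  # the unoriented plane is invariant; the directed aperture azimuth flips
  pl <- correct_overturn(plane_orientation(14, 155), 65)
  expect_equal(pl$dip_deg, 14, tolerance = 1e-12)
  expect_equal(pl$dip_direction_deg, 155, tolerance = 1e-12)
  ln <- line_orientation(144, 18, directed_azimuth_deg = 155)
  expect_equal(correct_overturn(ln, 65)$directed_azimuth_deg, (2 * 65 - 155) %% 360)

  # horizontal planes stay horizontal under any axis
  expect_equal(correct_overturn(plane_orientation(0, 123), 40)$dip_deg, 0)

  # double application is the identity
  set.seed(41)
  for (i in 1:50) {
    axis <- stats::runif(1, 0, 360)
    pl <- plane_orientation(stats::runif(1, 0, 90), stats::runif(1, 0, 360))
    back <- correct_overturn(correct_overturn(pl, axis), axis)
    expect_equal(back$dip_deg, pl$dip_deg, tolerance = 1e-12)
    if (pl$dip_deg > 1e-6)
      expect_equal(back$dip_direction_deg, pl$dip_direction_deg,
                   tolerance = 1e-9)
    ln <- line_orientation(stats::runif(1, 0, 360), stats::runif(1, 0, 90),
                           directed_azimuth_deg = stats::runif(1, 0, 360))
    back <- correct_overturn(correct_overturn(ln, axis), axis)
    expect_equal(back$trend_deg, ln$trend_deg, tolerance = 1e-9)
    expect_equal(back$plunge_deg, ln$plunge_deg, tolerance = 1e-9)
    expect_equal(back$directed_azimuth_deg, ln$directed_azimuth_deg,
                 tolerance = 1e-12)
  }
})

test_that("measure_orientations fills the orientation table and flags eligibility", {
  lm <- plane_landmarks(14, 155)
  tab <- data.frame(specimen_id = 1:3,
                    taxon = c("ammonoid", "ammonoid", "gastropod"),
                    Ax = lm$A[1], Ay = lm$A[2], Az = lm$A[3],
                    Bx = lm$B[1], By = lm$B[2], Bz = lm$B[3],
                    Cx = c(lm$C[1], lm$C[1], NA),
                    Cy = c(lm$C[2], lm$C[2], NA),
                    Cz = c(lm$C[3], lm$C[3], NA),
                    slice_count = c(6L, 3L, 2L))
  o <- measure_orientations(tab)
  expect_equal(o$dip_deg[1], 14, tolerance = 1e-9)
  expect_equal(o$dip_direction_deg[1], 155, tolerance = 1e-9)
  expect_true(is.na(o$dip_deg[3]))
  expect_equal(o$lineation_eligible, c(TRUE, FALSE, FALSE))
  expect_equal(o$plane_eligible, c(TRUE, TRUE, FALSE))
  expect_equal(o$gastropod_eligible, c(FALSE, FALSE, TRUE))
})
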