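# Lumbopelvic angle computations and landmark-level error metrics.

test_that("sacral slope matches direct trigonometric evaluation", {
  expect_equal(compute_SS(fixture_pelvis(c(10, 100), c(40, 100))), 0)
  expect_equal(compute_SS(fixture_pelvis(c(60, 70), c(30, 100))), 45)
  expect_equal(compute_SS(fixture_pelvis(c(50, 80), c(20, 90))),
               atan(10 / 30) * 180 / pi, tolerance = 1e-10)
  # degenerate endplate
  expect_error(compute_SS(fixture_pelvis(c(50, 80), c(50, 80))),
               class = "fedspine_geometry_error")
})

test_that("pelvic tilt is signed about the vertical through the femoral axis", {
  # M vertically above H
  lm <- fixture_pelvis(c(60, 99), c(40, 101), mid = c(50, 100), H = c(50, 150))
  expect_equal(compute_PT(lm), 0)
  # M posterior to H -> positive
  lm <- fixture_pelvis(c(60, 99), c(20, 101), mid = c(40, 100), H = c(50, 150))
  expect_equal(compute_PT(lm), atan(10 / 50) * 180 / pi, tolerance = 1e-10)
  # M anterior to H -> sign flip
  lm <- fixture_pelvis(c(80, 99), c(40, 101), mid = c(60, 100), H = c(50, 150))
  expect_equal(compute_PT(lm), -atan(10 / 50) * 180 / pi, tolerance = 1e-10)
  # degenerate: H == M
  lm <- fixture_pelvis(c(60, 99), c(40, 101), mid = c(50, 150), H = c(50, 150))
  expect_error(compute_PT(lm), class = "fedspine_geometry_error")
})

test_that("pelvic incidence closes the PI = PT + SS identity", {
  # SS = 0 with H vertically below M: perpendicular coincides with MH
  lm <- fixture_pelvis(c(70, 100), c(30, 100), H = c(50, 160))
  expect_equal(compute_PI(lm), 0)
  # constructed SS = 40, PT = 15
  lm2 <- build_landmarks(angle_set(SS = 40, PT = 15, LL = 50), morphology_seed = 3)
  expect_equal(compute_PI(lm2), 55, tolerance = 1e-7)
  expect_equal(compute_SS(lm2), 40, tolerance = 1e-7)
  expect_equal(compute_PT(lm2), 15, tolerance = 1e-7)
})

test_that("PI = PT + SS holds to 1e-6 degrees over random constructions", {
  worst <- 0
  for (i in 1:300) {
    lm <- random_lm(i)$lm
    worst <- max(worst, abs(compute_PI(lm) - compute_PT(lm) - compute_SS(lm)))
  }
  expect_lt(worst, 1e-6)
})

test_that("lumbar lordosis is the signed angle between endplates", {
  # parallel endplates -> 0
  a <- angle_set(SS = 35, PT = 10, LL = 0)
  lm <- build_landmarks(a, 5)
  expect_equal(compute_LL(lm), 0, tolerance = 1e-8)
  # L1 plate at 10 deg (opposite sense), sacral at 40 -> 50
  lm2 <- build_landmarks(angle_set(SS = 40, PT = 12, LL = 50), 6)
  expect_equal(compute_LL(lm2), 50, tolerance = 1e-8)
  # T12 convention is available and differs from L1 for curved spines
  expect_gt(abs(compute_LL(lm2, "T12") - compute_LL(lm2, "L1")), 1e-3)
})

test_that("angles agree with the rotate-to-horizontal brute-force oracle", {
  oracle <- function(lm) {
    s <- if (identical(lm$facing, "anterior_is_minus_x")) -1 else 1
    p <- lm$points
    M <- p["S1_mid", ]
    d <- p["S1_ant", ] - p["S1_post", ]
    phi <- atan2(d[[2]], s * d[[1]])  # signed plate inclination
    rot <- function(q) {              # rotate so the endplate reads horizontal
      v <- q - M
      c(cos(-phi) * s * v[[1]] - sin(-phi) * v[[2]],
        sin(-phi) * s * v[[1]] + cos(-phi) * v[[2]])
    }
    H <- rot((p["fem_head_L", ] + p["fem_head_R", ]) / 2)
    PI_o <- atan2(H[1], H[2]) * 180 / pi        # plate horizontal: perp is vertical
    d1 <- p["L1_asup", ] - p["L1_psup", ]
    phi1 <- atan2(d1[[2]], s * d1[[1]])
    list(SS = abs(phi) * 180 / pi, PI = PI_o, PT = PI_o - phi * 180 / pi,
         LL = (phi - phi1) * 180 / pi)
  }
  for (i in c(2, 9, 17, 33, 54)) {
    lm <- random_lm(i)$lm
    o <- oracle(lm)
    expect_equal(compute_SS(lm), o$SS, tolerance = 1e-9)
    expect_equal(compute_PT(lm), o$PT, tolerance = 1e-9)
    expect_equal(compute_PI(lm), o$PI, tolerance = 1e-9)
    expect_equal(compute_LL(lm), o$LL, tolerance = 1e-9)
  }
})

test_that("angles are invariant under translation and uniform scaling", {
  r <- random_lm(7)
  base <- unclass(compute_angles(r$lm))
  tr <- r$lm
  tr$points <- tr$points * 1.7 + 13.2
  tr$image_size <- tr$image_size * 3  # keep points in-field; irrelevant to angles
  expect_equal(unclass(compute_angles(tr)), base, tolerance = 1e-9)
})

test_that("mirroring flips PT unless facing is toggled", {
  r <- random_lm(12)
  W <- r$lm$image_size[1]
  mir <- r$lm
  mir$points[, 1] <- (W - 1) - mir$points[, 1]
  # facing not toggled: PT flips sign, SS unchanged
  expect_equal(compute_PT(mir), -compute_PT(r$lm), tolerance = 1e-9)
  expect_equal(compute_SS(mir), compute_SS(r$lm), tolerance = 1e-9)
  # facing toggled: all four angles unchanged
  mir$facing <- "anterior_is_minus_x"
  expect_equal(unclass(compute_angles(mir)), unclass(compute_angles(r$lm)),
               tolerance = 1e-9)
})

test_that("landmark error converts pixels to mm and averages per level", {
  r <- random_lm(3)
  gt <- r$lm
  gt$pixel_spacing_mm <- 0.5
  pred <- gt
  expect_true(all(landmark_error(pred, gt)$per_point == 0))
  # one point offset by a 3-4-5 triangle at 0.5 mm/px
  pred$points["L3_asup", ] <- pred$points["L3_asup", ] + c(3, 4)
  le <- landmark_error(pred, gt)
  expect_equal(unname(le$per_point[["L3_asup"]]), 2.5)
  expect_equal(sum(le$per_point > 0), 1)
  expect_equal(unname(le$per_level[["L3"]]), 2.5 / 4)  # mean over 4 corners
  # uniform shift: every per-level mean equals the shift length
  pred2 <- gt
  pred2$points[, 1] <- pred2$points[, 1] + 1
  gt2 <- gt; gt2$pixel_spacing_mm <- pred2$pixel_spacing_mm <- 1
  expect_true(all(abs(landmark_error(pred2, gt2)$per_level - 1) < 1e-12))
  # spacing mismatch is a unit error
  bad <- gt; bad$pixel_spacing_mm <- 1
  expect_error(landmark_error(bad, gt), class = "fedspine_unit_error")
})

test_that("per-point landmark error is a metric", {
  a <- random_lm(41)$lm; a$pixel_spacing_mm <- 1
  b <- random_lm(42)$lm; b$pixel_spacing_mm <- 1
  c_ <- random_lm(43)$lm; c_$pixel_spacing_mm <- 1
  dab <- landmark_error(a, b)$per_point
  dba <- landmark_error(b, a)$per_point
  dac <- landmark_error(a, c_)$per_point
  dcb <- landmark_error(c_, b)$per_point
  expect_equal(dab, dba)
  expect_true(all(dab >= 0))
  expect_true(all(landmark_error(a, a)$per_point == 0))
  expect_true(all(dab <= dac + dcb + 1e-12))
})

test_that("angle absolute error is the per-angle absolute difference", {
  g <- angle_set(SS = 40, PT = 5, LL = 50)
  p <- angle_set(SS = 45, PT = -5, LL = 50)
  e <- angle_abs_error(p, g)
  expect_equal(unname(e[c("SS", "PT", "LL")]), c(5, 10, 0))
  expect_true(all(angle_abs_error(g, g) == 0))
})
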