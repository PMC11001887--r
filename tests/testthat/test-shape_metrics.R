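test_that("circularity matches closed forms", {
  expect_equal(circularity(circle_polygon(3, 360)), 1, tolerance = 1e-3)
  expect_equal(circularity(unit_square()), pi / 4, tolerance = 1e-12)
  expect_equal(circularity(regular_hexagon()), pi * sqrt(3) / 6,
               tolerance = 1e-12)
})

test_that("circularity obeys the isoperimetric bound and scale invariance", {
  set.seed(8)
  for (i in 1:20) {
    p <- random_star_polygon(sample(8:40, 1))
    ci <- circularity(p)
    expect_lte(ci, 1)
    expect_equal(circularity(boundary_polygon(3.7 * unclass(p))), ci,
                 tolerance = 1e-12)
  }
  # adding an outward lobe to a convex shape strictly lowers circularity
  base <- make_ruffled_polygon(5, 0, 0, 240)
  lobes <- vapply(c(0, 0.1, 0.2, 0.3), function(a)
    circularity(make_ruffled_polygon(5, 5, a, 240)), numeric(1))
  expect_true(all(diff(lobes) < 0))
  expect_equal(lobes[1], circularity(base))
})

test_that("cell_volume and flatten_ratio evaluate the printed formulas", {
  g <- cell_geometry3d(100, 400, 10)
  expect_equal(cell_volume(g), 10 * (100 + 200 + 400) / 3, tolerance = 1e-12)
  expect_equal(flatten_ratio(g), sqrt(500) / 10, tolerance = 1e-12)
  # prism limit
  gp <- cell_geometry3d(57, 57, 3)
  expect_equal(cell_volume(gp), 3 * 57, tolerance = 1e-12)
  # 1000 random positive triples against an inline re-evaluation
  set.seed(13)
  for (i in 1:1000) {
    s <- stats::runif(3, 0.1, 500)
    gg <- cell_geometry3d(s[1], s[2], s[3])
    expect_equal(cell_volume(gg),
                 s[3] * (s[1] + sqrt(s[1] * s[2]) + s[2]) / 3,
                 tolerance = 1e-12)
    expect_equal(flatten_ratio(gg), sqrt(s[1] + s[2]) / s[3],
                 tolerance = 1e-12)
  }
  expect_error(cell_geometry3d(1, 1, 0), "positive")
})

test_that("detect_ruffles finds de novo arcs only", {
  circ0 <- make_ruffled_polygon(5, 0, 0, 200, frame_time = 0)
  circ1 <- make_ruffled_polygon(5, 0, 0, 200, frame_time = 1)
  expect_identical(nrow(detect_ruffles(list(circ0, circ1))), 0L)

  rose <- make_ruffled_polygon(5, 5, 0.2, 200, frame_time = 1)
  ev <- detect_ruffles(list(circ0, rose))
  expect_identical(nrow(ev), 5L)
  # lobe orientations of the unrotated rose sit at multiples of 72 degrees
  expect_equal(sort(ev$orientation_deg), c(0, 72, 144, 216, 288),
               tolerance = 4)
  # a persistent lobe is counted once (second appearance is not de novo)
  rose2 <- make_ruffled_polygon(5, 5, 0.2, 200, frame_time = 2)
  ev3 <- detect_ruffles(list(circ0, rose, rose2))
  expect_identical(nrow(ev3), 5L)
})

test_that("ruffle_rose bins and conserves events", {
  expect_identical(unname(ruffle_rose(15)), c(1L, rep(0L, 11)))
  expect_identical(unname(ruffle_rose(seq(0, 330, by = 30))), rep(1L, 12))
  set.seed(2)
  ang <- stats::runif(57, 0, 360)
  expect_identical(sum(ruffle_rose(ang)), 57L)
  expect_error(ruffle_rose(c(12, 400)), "\\[0, 360\\)")
})

test_that("migration_kinematics reports distance and per-axis velocities", {
  k <- migration_kinematics(rbind(c(0, 0), c(10, 0)), c(0, 10))
  expect_equal(c(k$distance, k$v_ap, k$v_dv), c(10, 1, 0))
  k2 <- migration_kinematics(rbind(c(1, 1), c(1, 1), c(1, 1)), c(0, 1, 2))
  expect_equal(c(k2$distance, k2$v_ap, k2$v_dv), c(0, 0, 0))
  k3 <- migration_kinematics(rbind(c(0, 0), c(3, 4)), c(0, 5))
  expect_equal(c(k3$distance, k3$v_ap, k3$v_dv), c(5, 0.6, 0.8))
  expect_error(migration_kinematics(rbind(c(0, 0), c(1, 1)), c(2, 2)),
               "zero elapsed")
})

test_that("autocorr_period finds the oscillation period", {
  tt <- seq(0, 30, by = 0.5)
  tr <- signal_trace(sin(2 * pi * tt / 6), 0.5)
  expect_equal(autocorr_period(tr), 6, tolerance = 0.5)
  # offset invariance (mean removal)
  tr2 <- signal_trace(sin(2 * pi * tt / 6) + 42, 0.5)
  expect_equal(autocorr_period(tr2), autocorr_period(tr))
  expect_message(p <- autocorr_period(signal_trace(rep(1, 50), 1)),
                 "no period")
  expect_true(is.na(p))
})

test_that("bleach_correct honours the 5% trigger and undoes the decay", {
  # flat background: returned unchanged
  tr <- signal_trace(c(5, 7, 6, 8), 1)
  bg <- signal_trace(rep(2, 4), 1)
  expect_identical(bleach_correct(tr, bg), tr)
  # adjacent drops below 5%: returned unchanged even though decaying
  slow <- make_bleached_trace(signal_trace(rep(100, 61), 0.5), 0.02)
  expect_identical(bleach_correct(slow$observed, slow$background)$values,
                   slow$observed$values)
  # triggered: constant signal recovered within 2%
  fast <- make_bleached_trace(signal_trace(rep(100, 21), 3), 0.02)
  corr <- bleach_correct(fast$observed, fast$background)
  expect_lt(diff(range(corr$values)) / 100, 0.02)
  # peak location restored for a unique-peak pulse under monotone decay
  tt <- seq(0, 60, 3)
  base <- signal_trace(100 + 80 * exp(-(tt - 36)^2 / (2 * 8^2)), 3)
  bl <- make_bleached_trace(base, 0.03)
  expect_false(which.max(bl$observed$values) == which.max(base$values))
  expect_identical(which.max(bleach_correct(bl$observed, bl$background)$values),
                   which.max(base$values))
  expect_error(bleach_correct(tr, signal_trace(c(1, -1, 1, 1), 1)),
               "positive")
})

test_that("fiber_polarity recovers constructed orientations", {
  f0 <- fiber_polarity(make_fiber_image(64, c("0" = 1), seed = 3))
  expect_equal(f0$dominant_deg, 0)
  f90 <- fiber_polarity(make_fiber_image(64, c("90" = 1), seed = 2))
  expect_equal(f90$dominant_deg, 90)
  expect_identical(dim(f90$dv_image), c(64L, 64L))
  # 50/50 mix: two modes of comparable mass
  for (s in 1:3) {
    h <- fiber_polarity(make_fiber_image(96, c("0" = 0.5, "90" = 0.5),
                                         n_lines = 60, seed = s))$histogram
    ratio <- sum(h[c("165", "0", "15")]) / sum(h[c("75", "90", "105")])
    expect_gt(ratio, 0.5)
    expect_lt(ratio, 2)
  }
  expect_error(fiber_polarity(matrix(1, 32, 32)), "foreground")
})

test_that("phase_segment locates constructed change-points", {
  tr <- signal_trace(c(rep(1, 21), 1 - cumsum(rep(0.01, 60)),
                       0.4 + cumsum(rep(0.03, 20))), 1)
  ps <- phase_segment(tr)
  expect_equal(ps$ruffling_onset, 20, tolerance = 2)
  expect_equal(ps$increasing_onset, 80, tolerance = 2)
  # invariant to uniform scaling
  ps2 <- phase_segment(signal_trace(5 * tr$values, 1))
  expect_identical(ps2, ps)
  # pure rise: no ruffling onset
  expect_message(mono <- phase_segment(signal_trace(seq(0, 1, 0.01), 1)),
                 "no transition")
  expect_true(is.na(mono$ruffling_onset))
})
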