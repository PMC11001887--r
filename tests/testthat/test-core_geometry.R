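test_that("boundary_polygon enforces its invariants", {
  expect_error(boundary_polygon(rbind(c(0, 0), c(1, 0))), "at least 3")
  expect_error(boundary_polygon(rbind(c(0, 0), c(0, 0), c(1, 1))),
               "duplicated")
  expect_error(boundary_polygon(rbind(c(0, 0), c(1, 1), c(2, 2))),
               "degenerate")
  # clockwise input is re-oriented counter-clockwise
  cw <- boundary_polygon(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)))
  expect_gt(folliclewave:::signed_area(unclass(cw)), 0)
})

test_that("polygon_measures matches closed forms and a triangulation oracle", {
  sq <- polygon_measures(unit_square())
  expect_equal(sq$area, 1, tolerance = 1e-12)
  expect_equal(sq$perimeter, 4, tolerance = 1e-12)
  expect_equal(sq$centroid, c(0.5, 0.5), tolerance = 1e-12)

  hx <- polygon_measures(regular_hexagon())
  expect_equal(hx$area, 3 * sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(hx$perimeter, 6, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:5) {
    p <- random_star_polygon(12)
    expect_equal(polygon_measures(p)$area, fan_triangulation_area(p),
                 tolerance = 1e-9)
  }
})

test_that("area is rigid-motion invariant and scales quadratically", {
  set.seed(3)
  p <- random_star_polygon(15)
  a0 <- polygon_measures(p)$area
  th <- 0.73
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- boundary_polygon(unclass(p) %*% R +
                              matrix(c(5, -2), nrow(p), 2, byrow = TRUE))
  expect_equal(polygon_measures(moved)$area, a0, tolerance = 1e-9)
  for (s in c(0.5, 2, 3.7))
    expect_equal(polygon_measures(boundary_polygon(s * unclass(p)))$area,
                 s^2 * a0, tolerance = 1e-9)
})

test_that("discrete_curvature recovers circle curvature with the outward sign", {
  for (R in c(5, 10)) {
    kap <- discrete_curvature(circle_polygon(R, 360), smooth_window = 3)
    expect_true(all(abs(kap - 1 / R) / (1 / R) < 0.02))
  }
})

test_that("curvature integrates to 2*pi over convex polygons", {
  set.seed(21)
  for (i in 1:5) {
    th <- sort(stats::runif(150, 0, 2 * pi))
    ab <- stats::runif(2, 2, 5)
    p <- boundary_polygon(cbind(ab[1] * cos(th), ab[2] * sin(th)))
    kap <- discrete_curvature(p, smooth_window = 1)
    v <- unclass(p); n <- nrow(v)
    jn <- c(2:n, 1); jp <- c(n, 1:(n - 1))
    ds <- (sqrt(rowSums((v[jn, ] - v)^2)) + sqrt(rowSums((v - v[jp, ])^2))) / 2
    expect_equal(sum(kap * ds), 2 * pi, tolerance = 0.02)
  }
})

test_that("five-lobed rose shows exactly five high-curvature arcs", {
  rose <- make_ruffled_polygon(base_radius = 5, n_lobes = 5, amplitude = 0.2,
                               n_points = 200)
  kap <- discrete_curvature(rose, smooth_window = 3)
  expect_identical(n_circular_arcs(kap > 1 / 5), 5L)
  # and between-lobe arcs are concave (negative curvature present)
  expect_true(any(kap < 0))
})

test_that("curvature argument validation", {
  p <- circle_polygon(1, 12)
  expect_error(discrete_curvature(p, 2), "odd")
  expect_error(discrete_curvature(p, 13), "smaller than the vertex count")
})

test_that("outward_normal points away from the interior", {
  circ <- circle_polygon(1, 360)
  i_right <- which.max(unclass(circ)[, 1])
  expect_equal(outward_normal(circ, i_right), c(1, 0), tolerance = 1e-4)
  i_top <- which.max(unclass(circ)[, 2])
  expect_equal(outward_normal(circ, i_top), c(0, 1), tolerance = 1e-4)

  set.seed(5)
  for (i in 1:5) {
    th <- sort(stats::runif(30, 0, 2 * pi))
    p <- boundary_polygon(cbind(3 * cos(th), 2 * sin(th)))  # convex
    cen <- polygon_measures(p)$centroid
    nor <- outward_normal(p)
    v <- unclass(p)
    radial <- v - matrix(cen, nrow(v), 2, byrow = TRUE)
    expect_true(all(rowSums(nor * radial) > 0))
  }
})

test_that("hexagonal_tiling builds a shared-vertex tissue without gaps", {
  m1 <- hexagonal_tiling(1, 1, 1.0, 1)
  expect_length(m1$cells, 1L)
  expect_equal(polygon_measures(mesh_cell_polygon(m1, 1))$area,
               3 * sqrt(3) / 2, tolerance = 1e-12)

  m <- hexagonal_tiling(3, 3, 1.0, 4)
  expect_length(m$cells, 9L)
  # every loop is a valid CCW boundary polygon with 6*4 vertices
  for (ci in 1:9) {
    poly <- mesh_cell_polygon(m, ci)
    expect_s3_class(poly, "boundary_polygon")
    expect_identical(nrow(poly), 24L)
  }
  # adjacency audit: vertices shared by two cells exist, and any two
  # neighbouring cells share a full subdivided edge (verts_per_edge + 1)
  counts <- lengths(m$adjacency)
  expect_true(any(counts == 2L))
  expect_true(all(counts >= 1L & counts <= 3L))
  shared_sizes <- integer(0)
  for (a in 1:8) for (b in (a + 1):9) {
    common <- length(intersect(m$cells[[a]], m$cells[[b]]))
    if (common > 2) shared_sizes <- c(shared_sizes, common)
  }
  expect_true(all(shared_sizes == 5L))  # 4 edge vertices + closing corner
  # no gaps/overlap: union area equals sum of cell areas on the hull
  cell_areas <- vapply(1:9, function(ci)
    polygon_measures(mesh_cell_polygon(m, ci))$area, numeric(1))
  expect_equal(sum(cell_areas), 9 * 3 * sqrt(3) / 2, tolerance = 1e-9)
  # anchors start on the vertices
  expect_identical(m$anchors, m$pool)
})

test_that("hexagonal_tiling rejects non-positive sizes", {
  expect_error(hexagonal_tiling(0, 3), ">= 1")
  expect_error(hexagonal_tiling(2, 2, -1), "positive")
})

test_that("axis_frame demands orthonormal axes", {
  af <- axis_frame(c(2, 0))
  expect_equal(af$ap_unit, c(1, 0))
  expect_equal(af$dv_unit, c(0, 1))
  expect_error(axis_frame(c(1, 0), c(1, 0.5)), "orthogonal")
})
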