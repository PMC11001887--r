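test_that("force_tension matches its examples and energy gradient", {
  expect_equal(force_tension(c(0, 0), c(1, 0), c(-1, 0), 1), c(0, 0))
  expect_equal(force_tension(c(0, 0), c(1, 0), c(0, 1), 1), c(1, 1))

  set.seed(31)
  K_L <- 0.05
  for (rep in 1:5) {
    p <- random_star_polygon(20)
    v <- unclass(p); n <- nrow(v)
    energy <- function(vv) {
      jn <- c(2:n, 1)
      K_L / 2 * sum((vv[jn, ] - vv)^2)
    }
    g <- num_gradient(energy, v)
    for (i in c(1, 7, 14)) {
      ip <- ((i - 2) %% n) + 1; im <- (i %% n) + 1
      f <- force_tension(v[i, ], v[ip, ], v[im, ], K_L)
      expect_lt(sqrt(sum((f + g[i, ])^2)) / sqrt(sum(g[i, ]^2)), 1e-4)
    }
  }
})

test_that("force_area: sign, magnitude example, and gradient discretization", {
  sq <- unit_square()
  # at target area the force vanishes
  expect_equal(force_area(sq, 1, K_a = 0.2, A0 = 1), c(0, 0))
  # inflated square: literal cortical magnitude K_a * s_hat * dA, inward
  s <- sqrt(1.1)  # side of a square inflated to area 1.1*A0
  sq2 <- boundary_polygon(s * unclass(sq))
  for (i in 1:4) {
    f <- force_area(sq2, i, K_a = 2, A0 = 1, method = "cortical")
    nor <- outward_normal(sq2, i)
    expect_lt(sum(f * nor), 0)  # restoring inward
    expect_equal(sqrt(sum(f^2)), 2 * s * 0.1, tolerance = 1e-9)
  }
  # gradient form is exactly minus the numerical gradient of K_a/2 (A-A0)^2
  set.seed(41)
  for (rep in 1:5) {
    p <- random_star_polygon(20)
    v <- unclass(p); n <- nrow(v)
    A0 <- polygon_measures(p)$area * 0.9
    K_a <- 0.01
    energy <- function(vv) {
      jn <- c(2:n, 1)
      A <- sum(vv[, 1] * vv[jn, 2] - vv[jn, 1] * vv[, 2]) / 2
      K_a / 2 * (A - A0)^2
    }
    g <- num_gradient(energy, v)
    f <- force_area(p, seq_len(n), K_a, A0, method = "gradient")
    expect_lt(max(sqrt(rowSums((f + g)^2))) / max(sqrt(rowSums(g^2))), 1e-4)
  }
  # the two discretizations agree on finely sampled boundaries
  circ <- circle_polygon(5, 200)
  fc <- force_area(circ, 1:200, 0.01, 70, method = "cortical")
  fg <- force_area(circ, 1:200, 0.01, 70, method = "gradient")
  expect_lt(max(sqrt(rowSums((fc - fg)^2))) / max(sqrt(rowSums(fc^2))), 0.01)
})

test_that("force_rac has the stated pulse envelope", {
  f_Rac <- 3; sigma <- 4; T_cycle <- 20
  nor <- c(0, 1)
  peak <- force_rac(10, 0, f_Rac, sigma, T_cycle, nor)
  expect_equal(peak, (f_Rac / (sigma * sqrt(2 * pi))) * nor, tolerance = 1e-12)
  expect_equal(force_rac(10, 0, f_Rac, sigma, T_cycle, nor, active = FALSE),
               c(0, 0))
  expect_equal(force_rac(25, 0, f_Rac, sigma, T_cycle, nor), c(0, 0))
  # magnitude at T/2 +- sigma is peak * exp(-1/2), symmetric about mid-pulse
  lo <- force_rac(10 - sigma, 0, f_Rac, sigma, T_cycle, nor)
  hi <- force_rac(10 + sigma, 0, f_Rac, sigma, T_cycle, nor)
  expect_equal(lo, hi, tolerance = 1e-12)
  expect_equal(sqrt(sum(lo^2)), sqrt(sum(peak^2)) * exp(-0.5),
               tolerance = 1e-12)
})

test_that("force_adhesion implements the Hill gate", {
  expect_equal(force_adhesion(c(1, 2), c(3, 5), 1, 0, 1, 2), c(0, 0))
  # half saturation at L_Rho^n = K_d
  f <- force_adhesion(c(0, 0), c(2, -1), f_CAMs = 4, L_Rho = sqrt(3),
                      K_d = 3, n = 2)
  expect_equal(f, 0.5 * 4 * c(2, -1), tolerance = 1e-12)
  # monotone non-decreasing in L_Rho
  grid <- seq(0, 5, by = 0.25)
  mag <- vapply(grid, function(L)
    force_adhesion(c(0, 0), c(1, 0), 1, L, 1.7, 3)[1], numeric(1))
  expect_true(all(diff(mag) >= 0))
  expect_error(force_adhesion(c(0, 0), c(1, 0), 1, -1, 1, 2), "non-negative")
})

test_that("force_fiber is a one-sided action-reaction pair", {
  expect_equal(force_fiber(c(0, 0), c(0, 3), 2, 3)$f_a, c(0, 0))
  expect_equal(force_fiber(c(0, 0), c(0, 1.5), 2, 3)$f_a, c(0, 0))
  f <- force_fiber(c(0, 0), c(0, 4), K_Fiber = 2, L0 = 3)
  expect_equal(f$f_a, c(0, 2), tolerance = 1e-12)
  expect_equal(f$f_a + f$f_b, c(0, 0))
  expect_error(force_fiber(c(1, 1), c(1, 1), 1, 1), "coincident")
})

test_that("force_noise is seeded and has the right moments", {
  expect_equal(force_noise(0), c(0, 0))
  set.seed(99)
  draws <- matrix(replicate(1e5, force_noise(0.5)), ncol = 2, byrow = TRUE)
  expect_true(all(abs(colMeans(draws)) < 3 * 0.5 / sqrt(1e5)))
  expect_true(all(abs(apply(draws, 2, stats::var) - 0.25) / 0.25 < 0.05))
})

test_that("the integrator agrees with the R force functions on one step", {
  p <- model_params(f_Rac = 0, f_R = 0)
  st <- sim_init("WT", "combined_factor", params = p, seed = 2,
                 n_rows = 1, n_cols = 1, edge_len = 5, verts_per_edge = 4)
  poly <- boundary_polygon(st$pos[st$cells[[1]], ])
  n <- nrow(poly)
  f_exp <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    ip <- ((i - 2) %% n) + 1; im <- (i %% n) + 1
    v <- unclass(poly)
    f_exp[i, ] <- force_tension(v[i, ], v[ip, ], v[im, ], p$K_L) +
      force_area(poly, i, p$K_a, st$A0[1], method = "cortical")
    # anchors coincide with vertices and fibers sit at L0: both contribute 0
  }
  p_small <- p; p_small$frame_dt <- p$dt  # one macro step = one dt step
  st$params <- p_small
  st2 <- sim_advance(st, p$dt)
  moved <- (st2$pos - st$pos)[st$cells[[1]], ]
  expect_equal(moved, (p$dt / p$eta_vis) * f_exp, tolerance = 1e-10)
})

test_that("a state with vanishing forces is a fixed point of step", {
  p <- model_params(K_L = 1e-15, f_Rac = 0, f_R = 0)
  st <- sim_init("WT", "combined_factor", params = p, seed = 3,
                 n_rows = 2, n_cols = 2)
  st2 <- sim_advance(st, 5)
  expect_lt(max(abs(st2$pos - st$pos)), 1e-10)
})

test_that("trajectories are deterministic and translation-covariant", {
  p <- model_params(f_R = 0)
  mk <- function(shift = c(0, 0)) {
    st <- sim_init("WT", "combined_factor", params = p, seed = 4,
                   n_rows = 2, n_cols = 2)
    st$pos <- st$pos + matrix(shift, nrow(st$pos), 2, byrow = TRUE)
    st$anc <- st$anc + matrix(shift, nrow(st$anc), 2, byrow = TRUE)
    st$x_post <- st$x_post + shift[1]
    st
  }
  set.seed(17); a <- sim_advance(mk(), 30)
  set.seed(17); b <- sim_advance(mk(), 30)
  expect_identical(a$pos, b$pos)
  set.seed(17); d <- sim_advance(mk(c(3, -2)), 30)
  expect_equal(d$pos - a$pos, matrix(c(3, -2), nrow(a$pos), 2, byrow = TRUE),
               tolerance = 1e-9)
})

test_that("apply_oocyte_growth stretches anchors about the posterior edge", {
  st <- sim_init("WT", seed = 1, n_rows = 1, n_cols = 2)
  anc0 <- st$anc
  expect_equal(apply_oocyte_growth(st, 0, dt = 1)$anc, anc0)
  st2 <- apply_oocyte_growth(st, 0.01, dt = 1)
  d0 <- st$x_post - anc0[, 1]             # distance from posterior edge
  expect_equal(st2$anc[, 1], st$x_post - d0 * 1.01, tolerance = 1e-12)
  # an anchor 10 um from the posterior edge moves 0.1 um anteriorly
  i <- which.min(abs(d0 - 10))
  expect_equal(anc0[i, 1] - st2$anc[i, 1], d0[i] * 0.01, tolerance = 1e-12)
  # D-V coordinates never change
  expect_identical(st2$anc[, 2], anc0[, 2])
})

test_that("run_protocol validates genotypes and records the mode contract", {
  expect_error(run_protocol("NOPE", seed = 1), "presets")
  p <- model_params()
  single <- run_protocol("Rho1DN", "single_factor", seed = 1,
                         n_rows = 1, n_cols = 2, total_minutes = 2)
  combined <- run_protocol("Rho1DN", "combined_factor", seed = 1,
                           n_rows = 1, n_cols = 2, total_minutes = 2)
  expect_equal(single$manifest$g_used, p$g_WT)
  expect_equal(combined$manifest$g_used, p$g_WT * genotype("Rho1DN")$g_mult)
  # dumping inhibition is the one single factor that touches g itself
  dump <- run_protocol("DumpingInhibited", "single_factor", seed = 1,
                       n_rows = 1, n_cols = 2, total_minutes = 2)
  expect_equal(dump$manifest$g_used,
               p$g_WT * genotype("DumpingInhibited")$g_mult)
  # Rac inhibition: 40-min ruffling only in combined mode
  expect_equal(run_protocol("Rac1DN_weak", "single_factor", seed = 1,
                            n_rows = 1, n_cols = 2,
                            total_minutes = 2)$manifest$ruffling_duration, 60)
  expect_equal(run_protocol("Rac1DN_weak", "combined_factor", seed = 1,
                            n_rows = 1, n_cols = 2,
                            total_minutes = 2)$manifest$ruffling_duration, 40)
})

test_that("a WT run shows the qualitative phase behavior", {
  sim <- cached_run("WT", 1)
  ts <- sim$tissue_summary
  ruff <- ts$time_min <= 60
  expect_lt(min(ts$mean_circularity[ruff]), ts$mean_circularity[1] - 0.02)
  late <- ts$time_min >= 80
  expect_gt(mean(ts$mean_circularity[late]), min(ts$mean_circularity[ruff]))
  expect_gt(ts$mean_area_um2[nrow(ts)], ts$mean_area_um2[1])
})
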