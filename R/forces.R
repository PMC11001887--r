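#' Cortical line tension on one vertex
#'
#' Zero-rest-length spring reading of the cortical tension: the force on a
#' vertex is `K_L * (s_plus + s_minus)` where `s_plus`/`s_minus` are the
#' full vectors from the vertex to its two cortex neighbours. This is
#' exactly minus the gradient of the energy `K_L/2 * sum(|edge|^2)`.
#'
#' @param vertex,prev_neighbor,next_neighbor length-2 positions (um).
#' @param K_L line tension (force/um).
#' @return length-2 force vector.
#' @export
force_tension <- function(vertex, prev_neighbor, next_neighbor, K_L) {
  K_L * ((next_neighbor - vertex) + (prev_neighbor - vertex))
}

#' Areal elastic restoring force on one vertex
#'
#' `F = -K_a * s_hat * (A - A0) * r_nor`, with `s_hat` the coverage cortical
#' length of the vertex (half-sum of its two adjacent edge lengths) and
#' `r_nor` the outward unit normal; inward when the cell is inflated beyond
#' its target area `A0`. Two discretizations are provided: `"cortical"` is
#' the literal reading above (the simulator default); `"gradient"` replaces
#' `s_hat * r_nor` by `perp(p_next - p_prev) / 2`, which makes the force the
#' exact negative gradient of `K_a/2 * (A - A0)^2`. The two agree to second
#' order in the vertex spacing (they are identical when the two adjacent
#' edges are collinear and equal).
#'
#' @param poly a [boundary_polygon()] for the cell.
#' @param vertex_index vertex at which to evaluate (1-based; may be a vector).
#' @param K_a areal elastic modulus (force/um^3).
#' @param A0 target area (um^2).
#' @param method `"cortical"` or `"gradient"` (see Details).
#' @return length-2 force vector (or n x 2 matrix for several indices).
#' @export
force_area <- function(poly, vertex_index, K_a, A0,
                       method = c("cortical", "gradient")) {
  method <- match.arg(method)
  v <- as_poly_matrix(poly)
  n <- nrow(v)
  A <- signed_area(v)
  i <- as.integer(vertex_index)
  ip <- ((i - 2) %% n) + 1
  im <- (i %% n) + 1
  if (method == "cortical") {
    sp <- v[im, , drop = FALSE] - v[i, , drop = FALSE]
    sm <- v[ip, , drop = FALSE] - v[i, , drop = FALSE]
    s_hat <- (sqrt(rowSums(sp^2)) + sqrt(rowSums(sm^2))) / 2
    nor <- outward_normal(poly, i)
    if (length(i) == 1L) nor <- matrix(nor, 1)
    f <- -K_a * (A - A0) * s_hat * nor
  } else {
    t_ <- v[im, , drop = FALSE] - v[ip, , drop = FALSE]
    f <- -K_a * (A - A0) * cbind(t_[, 2], -t_[, 1]) / 2
  }
  if (length(i) == 1L) as.numeric(f) else f
}

#' Rac1 protrusion pulse force
#'
#' During an activated Rac cycle of duration `T_cycle`, an active membrane
#' vertex is pushed outward with a Gaussian envelope centred at mid-cycle:
#' `F = f_Rac / (sigma*sqrt(2*pi)) * exp(-((2*tau - T)/(2*sigma))^2 / 2) * r_nor`
#' with `tau = t - pulse_start`. Outside the cycle window, or on an inactive
#' vertex, the force is zero. The peak magnitude at `tau = T/2` is
#' `f_Rac / (sigma*sqrt(2*pi))`.
#'
#' @param t current time (min).
#' @param pulse_start cycle start time (min).
#' @param f_Rac pulse strength (force.min).
#' @param sigma pulse standard deviation (min).
#' @param T_cycle cycle duration (min).
#' @param r_nor outward unit normal at the vertex.
#' @param active logical; is the vertex in the Rac-recruited segment?
#' @return length-2 force vector.
#' @export
force_rac <- function(t, pulse_start, f_Rac, sigma, T_cycle, r_nor,
                      active = TRUE) {
  if (sigma <= 0 || T_cycle <= 0) stop("sigma and T_cycle must be positive")
  tau <- t - pulse_start
  if (!active || tau < 0 || tau > T_cycle) return(c(0, 0))
  mag <- f_Rac / (sigma * sqrt(2 * pi)) *
    exp(-0.5 * ((2 * tau - T_cycle) / (2 * sigma))^2)
  mag * r_nor
}

#' Hill-gated focal-adhesion force
#'
#' Adhesion acts as a spring from the vertex to its substrate anchor, gated
#' by Rho activity through a Hill function:
#' `F = f_CAMs * L_Rho^n / (K_d + L_Rho^n) * (anchor - vertex)`.
#' At `L_Rho^n = K_d` the gate is at half saturation.
#'
#' @param vertex_pos,anchor_pos length-2 positions (um).
#' @param f_CAMs adhesion strength of the CAMs (force/um).
#' @param L_Rho RhoA GTPase concentration (>= 0).
#' @param K_d apparent dissociation constant (> 0).
#' @param n Hill coefficient (>= 1).
#' @return length-2 force vector, restoring toward the anchor.
#' @export
force_adhesion <- function(vertex_pos, anchor_pos, f_CAMs, L_Rho, K_d, n) {
  if (L_Rho < 0) stop("L_Rho must be non-negative")
  if (K_d <= 0) stop("K_d must be positive")
  if (n < 1) stop("Hill coefficient n must be >= 1")
  gate <- L_Rho^n / (K_d + L_Rho^n)
  f_CAMs * gate * (anchor_pos - vertex_pos)
}

#' One-sided stress-fiber spring
#'
#' D-V stress fibers resist extension beyond their rest length but cannot
#' sustain compression: for endpoint distance `L > L0` the endpoints are
#' pulled toward each other with magnitude `K_Fiber * (L - L0)` along the
#' fiber axis; for `L <= L0` the force is zero. The two forces are an exact
#' action-reaction pair.
#'
#' @param p_a,p_b fiber endpoint positions (um), distinct.
#' @param K_Fiber spring constant (force/um).
#' @param L0 rest ("critical") length (um).
#' @return list with `f_a` and `f_b`, the forces on the two endpoints.
#' @export
force_fiber <- function(p_a, p_b, K_Fiber, L0) {
  d <- p_b - p_a
  L <- sqrt(sum(d^2))
  if (L == 0) stop("coincident fiber endpoints")
  if (L <= L0) return(list(f_a = c(0, 0), f_b = c(0, 0)))
  u <- d / L
  mag <- K_Fiber * (L - L0)
  list(f_a = mag * u, f_b = -mag * u)
}

#' Thermal noise force
#'
#' `F = f_R * (g1, g2)` with independent standard normal components drawn
#' from the R random number generator (seed-reproducible).
#'
#' @param f_R noise strength (force).
#' @return length-2 force vector.
#' @export
force_noise <- function(f_R) {
  if (f_R == 0) return(c(0, 0))
  f_R * stats::rnorm(2)
}
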