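#include <Rcpp.h>
using namespace Rcpp;

// Overdamped finite-difference integrator for the modified vertex model.
//
// The tissue is flattened into per-entry arrays: one "entry" is one vertex
// occurrence inside one cell loop (shared vertices appear once per cell).
// Tension, area and Rac forces are accumulated per entry into the pool;
// adhesion and noise act per pool vertex; fibers act on endpoint pairs.
// All index vectors are 0-based. Noise uses the R RNG (seed-reproducible);
// when f_R == 0 no draws are consumed, so schedules stay aligned between
// noisy and noise-free runs.
//
// Substrate anchors are advected by oocyte A-P growth each step:
//   x <- x_post + (x - x_post) * (1 + g*dt)
// (x_post = posterior edge; growth stretches the matrix anteriorly).
// [[Rcpp::export]]
List fw_integrate(NumericMatrix pos0, NumericMatrix anc0,
                  IntegerVector ent_v, IntegerVector ent_prev,
                  IntegerVector ent_next, IntegerVector ent_cell,
                  NumericVector cell_A0, NumericVector A0_tau,
                  double K_L, double K_a,
                  NumericVector rac_amp, NumericVector rac_start,
                  double rac_sigma, double rac_T,
                  NumericVector adh_coef,
                  IntegerVector fib_a, IntegerVector fib_b,
                  NumericVector fib_L0, NumericVector fib_k,
                  double f_R, double eta, double dt, double t0, int nsteps,
                  double growth_g, double x_post) {
  const int nv = pos0.nrow();
  const int ne = ent_v.size();
  const int nc = cell_A0.size();
  const int nf = fib_a.size();

  NumericMatrix pos = clone(pos0);
  NumericMatrix anc = clone(anc0);
  NumericVector A0 = clone(cell_A0);
  std::vector<double> fx(nv), fy(nv), area(nc);
  const double rac_norm = 1.0 / (rac_sigma * std::sqrt(2.0 * M_PI));
  double t = t0;

  for (int step = 0; step < nsteps; ++step) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(area.begin(), area.end(), 0.0);

    // cell areas (shoelace over directed entry edges v -> next)
    for (int e = 0; e < ne; ++e) {
      int v = ent_v[e], w = ent_next[e];
      area[ent_cell[e]] += 0.5 * (pos(v, 0) * pos(w, 1) - pos(w, 0) * pos(v, 1));
    }

    for (int e = 0; e < ne; ++e) {
      const int v = ent_v[e], vp = ent_prev[e], vn = ent_next[e];
      const double x = pos(v, 0), y = pos(v, 1);
      const double spx = pos(vn, 0) - x, spy = pos(vn, 1) - y;
      const double smx = pos(vp, 0) - x, smy = pos(vp, 1) - y;

      // cortical tension: zero-rest-length springs to both neighbours
      fx[v] += K_L * (spx + smx);
      fy[v] += K_L * (spy + smy);

      // outward normal of the CCW loop: tangent (next - prev) rotated -90 deg
      const double tx = pos(vn, 0) - pos(vp, 0), ty = pos(vn, 1) - pos(vp, 1);
      const double tl = std::sqrt(tx * tx + ty * ty);
      if (tl <= 0.0) continue;
      const double nx = ty / tl, ny = -tx / tl;

      // areal elasticity, literal cortical-coverage discretization
      const double s_hat = 0.5 * (std::sqrt(spx * spx + spy * spy) +
                                  std::sqrt(smx * smx + smy * smy));
      const double fa = -K_a * s_hat * (area[ent_cell[e]] - A0[ent_cell[e]]);
      fx[v] += fa * nx;
      fy[v] += fa * ny;

      // Rac protrusion pulse (Gaussian envelope within the active cycle)
      if (rac_amp[e] > 0.0) {
        const double tau = t - rac_start[e];
        if (tau >= 0.0 && tau <= rac_T) {
          const double z = (2.0 * tau - rac_T) / (2.0 * rac_sigma);
          const double mag = rac_amp[e] * rac_norm * std::exp(-0.5 * z * z);
          fx[v] += mag * nx;
          fy[v] += mag * ny;
        }
      }
    }

    // Hill-gated adhesion springs toward substrate anchors
    for (int v = 0; v < nv; ++v) {
      fx[v] += adh_coef[v] * (anc(v, 0) - pos(v, 0));
      fy[v] += adh_coef[v] * (anc(v, 1) - pos(v, 1));
    }

    // one-sided D-V stress fibers (tension only, action-reaction pairs)
    for (int f = 0; f < nf; ++f) {
      if (fib_k[f] <= 0.0) continue;
      const int a = fib_a[f], b = fib_b[f];
      const double dx = pos(b, 0) - pos(a, 0), dy = pos(b, 1) - pos(a, 1);
      const double L = std::sqrt(dx * dx + dy * dy);
      if (L > fib_L0[f] && L > 0.0) {
        const double mag = fib_k[f] * (L - fib_L0[f]) / L;
        fx[a] += mag * dx; fy[a] += mag * dy;
        fx[b] -= mag * dx; fy[b] -= mag * dy;
      }
    }

    const double mob = dt / eta;
    if (f_R > 0.0) {
      for (int v = 0; v < nv; ++v) {
        fx[v] += f_R * norm_rand();
        fy[v] += f_R * norm_rand();
      }
    }
    for (int v = 0; v < nv; ++v) {
      pos(v, 0) += mob * fx[v];
      pos(v, 1) += mob * fy[v];
    }

    // plastic target area: basal flattening lets A0 track the attained
    // area on a slow timescale (0 = frozen target)
    for (int c = 0; c < nc; ++c)
      if (A0_tau[c] > 0.0)
        A0[c] += (dt / A0_tau[c]) * (area[c] - A0[c]);

    if (growth_g > 0.0) {
      const double s = 1.0 + growth_g * dt;
      for (int v = 0; v < nv; ++v)
        anc(v, 0) = x_post + (anc(v, 0) - x_post) * s;
    }
    t += dt;
  }

  for (int v = 0; v < nv; ++v)
    if (!std::isfinite(pos(v, 0)) || !std::isfinite(pos(v, 1)))
      stop("non-finite vertex position at t = %f (vertex %d); reduce dt", t, v + 1);

  return List::create(_["pos"] = pos, _["anc"] = anc, _["A0"] = A0,
                      _["t"] = t);
}
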