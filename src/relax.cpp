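#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Damped Newtonian relaxation of the wall-spring / turgor-pressure lattice.
// Identical update rule to the R reference path in relax_to_equilibrium():
// per iteration, accumulate spring forces k*(L-|d|) along each wall and
// per-cell pressure forces p_const*|e| along outward wall normals (split
// half to each endpoint), zero x-components on fixed vertices, test the
// residuals, then take one (semi-implicit) Euler step.
// [[Rcpp::export]]
List relax_cpp(NumericMatrix pos0, NumericMatrix vel0,
               IntegerVector wfrom, IntegerVector wto,
               NumericVector rest, NumericVector stiff,
               IntegerMatrix cellv, LogicalVector fixedx,
               double p_const, double beta, double mass,
               double dt, double tol, int maxit, bool semi) {
  const int nv = pos0.nrow();
  const int nw = wfrom.size();
  const int nc = cellv.nrow();
  std::vector<double> px(nv), py(nv), vx(nv), vy(nv), fx(nv), fy(nv);
  for (int i = 0; i < nv; ++i) {
    px[i] = pos0(i, 0); py[i] = pos0(i, 1);
    vx[i] = vel0(i, 0); vy[i] = vel0(i, 1);
  }
  // plain copies: avoid Rcpp element-access overhead in the hot loop
  std::vector<int> wu(nw), wv(nw);
  std::vector<double> wrest(nw), wk(nw);
  for (int w = 0; w < nw; ++w) {
    wu[w] = wfrom[w] - 1; wv[w] = wto[w] - 1;
    wrest[w] = rest[w]; wk[w] = stiff[w];
  }
  std::vector<int> cv(4 * nc);
  for (int c = 0; c < nc; ++c)
    for (int e = 0; e < 4; ++e) cv[4 * c + e] = cellv(c, e) - 1;
  std::vector<char> fixed(nv);
  for (int i = 0; i < nv; ++i) fixed[i] = fixedx[i] ? 1 : 0;
  int iters = 0;
  bool converged = false;
  double rf = NA_REAL, rv = NA_REAL;
  for (;;) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    for (int w = 0; w < nw; ++w) {
      const int u = wu[w], v = wv[w];
      const double dx = px[v] - px[u], dy = py[v] - py[u];
      const double len = std::sqrt(dx * dx + dy * dy);
      if (len < 1e-12)
        stop("degenerate geometry: coincident spring endpoints (iteration %d)",
             iters);
      const double m = wk[w] * (wrest[w] - len) / len;
      fx[u] -= m * dx; fy[u] -= m * dy;
      fx[v] += m * dx; fy[v] += m * dy;
    }
    for (int c = 0; c < nc; ++c) {
      const int *q = &cv[4 * c];
      for (int e = 0; e < 4; ++e) {
        const int a = q[e];
        const int b = q[(e + 1) & 3];
        const double ex = px[b] - px[a], ey = py[b] - py[a];
        // outward normal force p_const * |e| * (ey,-ex)/|e|, half per endpoint
        const double gx = 0.5 * p_const * ey;
        const double gy = -0.5 * p_const * ex;
        fx[a] += gx; fy[a] += gy;
        fx[b] += gx; fy[b] += gy;
      }
    }
    double maxf2 = 0.0, maxv2 = 0.0;
    for (int i = 0; i < nv; ++i) {
      if (fixed[i]) fx[i] = 0.0;
      const double f2 = fx[i] * fx[i] + fy[i] * fy[i];
      const double v2 = vx[i] * vx[i] + vy[i] * vy[i];
      if (f2 > maxf2) maxf2 = f2;
      if (v2 > maxv2) maxv2 = v2;
    }
    rf = std::sqrt(maxf2) / mass;
    rv = std::sqrt(maxv2);
    if (rf < tol && rv < tol) { converged = true; break; }
    if (iters >= maxit) break;
    for (int i = 0; i < nv; ++i) {
      const double nvx = vx[i] + dt * (fx[i] / mass - beta * vx[i]);
      const double nvy = vy[i] + dt * (fy[i] / mass - beta * vy[i]);
      const double sx = semi ? nvx : vx[i];
      const double sy = semi ? nvy : vy[i];
      double nx = px[i] + dt * sx;
      const double ny = py[i] + dt * sy;
      vx[i] = nvx; vy[i] = nvy;
      if (fixed[i]) { vx[i] = 0.0; nx = px[i]; }
      px[i] = nx; py[i] = ny;
      if (!std::isfinite(px[i]) || !std::isfinite(py[i]))
        stop("numerical blow-up: non-finite position at iteration %d",
             iters + 1);
    }
    ++iters;
  }
  NumericMatrix pos(nv, 2), vel(nv, 2);
  for (int i = 0; i < nv; ++i) {
    pos(i, 0) = px[i]; pos(i, 1) = py[i];
    vel(i, 0) = vx[i]; vel(i, 1) = vy[i];
  }
  return List::create(_["pos"] = pos, _["vel"] = vel,
                      _["iterations"] = iters,
                      _["converged"] = converged,
                      _["residual_force"] = rf,
                      _["residual_velocity"] = rv);
}
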