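#include <Rcpp.h>
using namespace Rcpp;

// Exact ray tracing of a pixel grid (Siddon-style incremental traversal).
//
// A ray with angle theta and radial offset r is the point set
//   u(s) = r * (cos theta, sin theta) + s * (-sin theta, cos theta),
// where s is the depth coordinate along the ray.  The grid covers
// [-fov/2, fov/2]^2 with nx columns (x) and ny rows (y); pixel (iy, ix)
// (0-based) covers x in [x0 + ix*d, x0 + (ix+1)*d) and likewise in y,
// d = fov/nx.  The image vector is the column-major [ny, nx] matrix,
// index iy + ny*ix; rays are enumerated with angle fastest, matching a
// column-major [n_angles, n_offsets] sinogram.
//
// The traversal accumulates the exact intersection length of each ray with
// each pixel, restricted to the depth window [s0, s1]; with an unbounded
// window this yields full line integrals, with a finite window the partial
// line integrals of one depth bin.
//
// [[Rcpp::export]]
List siddon_trace(int nx, int ny, double fov,
                  NumericVector angles, NumericVector offsets,
                  double s0, double s1) {
  const double x0 = -fov / 2.0, y0 = -fov / 2.0;
  const double d = fov / nx;
  const double tiny = 1e-9 * fov;
  const int na = angles.size(), nr = offsets.size();

  std::vector<int> ri, pj;
  std::vector<double> len;
  ri.reserve((size_t)na * nr * (nx + ny));
  pj.reserve((size_t)na * nr * (nx + ny));
  len.reserve((size_t)na * nr * (nx + ny));

  for (int ir = 0; ir < nr; ++ir) {
    const double r = offsets[ir];
    for (int ia = 0; ia < na; ++ia) {
      const double c = std::cos(angles[ia]), s = std::sin(angles[ia]);
      const double px = r * c, py = r * s;       // point at depth 0
      const double dx = -s, dy = c;              // unit depth direction

      // parametric window where the ray is inside the grid
      double lo = s0, hi = s1;
      if (std::fabs(dx) < 1e-14) {
        if (px < x0 || px > x0 + nx * d) continue;
      } else {
        double a = (x0 - px) / dx, b = (x0 + nx * d - px) / dx;
        if (a > b) std::swap(a, b);
        lo = std::max(lo, a); hi = std::min(hi, b);
      }
      if (std::fabs(dy) < 1e-14) {
        if (py < y0 || py > y0 + ny * d) continue;
      } else {
        double a = (y0 - py) / dy, b = (y0 + ny * d - py) / dy;
        if (a > b) std::swap(a, b);
        lo = std::max(lo, a); hi = std::min(hi, b);
      }
      if (hi - lo <= tiny) continue;

      // starting pixel, nudged inside to avoid boundary ambiguity
      double sx = px + (lo + tiny) * dx, sy = py + (lo + tiny) * dy;
      int ix = (int)std::floor((sx - x0) / d);
      int iy = (int)std::floor((sy - y0) / d);
      if (ix < 0) ix = 0; if (ix > nx - 1) ix = nx - 1;
      if (iy < 0) iy = 0; if (iy > ny - 1) iy = ny - 1;

      const int stepx = (dx > 1e-14) ? 1 : ((dx < -1e-14) ? -1 : 0);
      const int stepy = (dy > 1e-14) ? 1 : ((dy < -1e-14) ? -1 : 0);
      const double dtx = (stepx != 0) ? d / std::fabs(dx) : R_PosInf;
      const double dty = (stepy != 0) ? d / std::fabs(dy) : R_PosInf;

      double tx = R_PosInf, ty = R_PosInf;
      if (stepx > 0) tx = (x0 + (ix + 1) * d - px) / dx;
      else if (stepx < 0) tx = (x0 + ix * d - px) / dx;
      if (stepy > 0) ty = (y0 + (iy + 1) * d - py) / dy;
      else if (stepy < 0) ty = (y0 + iy * d - py) / dy;

      const int ray = ia + na * ir;  // 0-based ray index
      double scur = lo;
      while (scur < hi - tiny) {
        double snext = std::min(std::min(tx, ty), hi);
        double l = snext - scur;
        if (l > tiny) {
          ri.push_back(ray + 1);
          pj.push_back(iy + ny * ix + 1);
          len.push_back(l);
        }
        if (snext >= hi - tiny) break;
        if (tx <= ty) { ix += stepx; tx += dtx; }
        else          { iy += stepy; ty += dty; }
        if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) break;
        scur = snext;
      }
    }
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(pj),
                      _["x"] = wrap(len));
}
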