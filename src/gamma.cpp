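// 2D gamma-index map: for each reference pixel, minimum over a search disk
// of sqrt((dose diff / dose tol)^2 + (distance / dta)^2), with the
// evaluated image sampled on a sub-pixel grid by bilinear interpolation.
// Offsets are visited in order of increasing distance so the search can
// stop as soon as the distance term alone exceeds the current best gamma.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

struct Offset { double dx, dy, r2; };

// [[Rcpp::export(name = ".gamma_map_cpp")]]
NumericMatrix gamma_map_cpp(NumericMatrix ref, NumericMatrix ev,
                            double spacing, double dta,
                            double tol_global, double local_frac,
                            double search_radius, int upsample) {
  const int nr = ref.nrow(), nc = ref.ncol();
  const double step = spacing / upsample;
  const bool local = local_frac > 0.0;

  std::vector<Offset> offs;
  const int kmax = (int)std::floor(search_radius / step);
  for (int ki = -kmax; ki <= kmax; ++ki)
    for (int kj = -kmax; kj <= kmax; ++kj) {
      const double dx = ki * step, dy = kj * step, r2 = dx * dx + dy * dy;
      if (r2 <= search_radius * search_radius + 1e-12)
        offs.push_back(Offset{dx, dy, r2});
    }
  std::sort(offs.begin(), offs.end(),
            [](const Offset& a, const Offset& b) { return a.r2 < b.r2; });

  const double dta2 = dta * dta;
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      const double dref = ref(i, j);
      const double tol = local ? local_frac * dref : tol_global;
      double best = R_PosInf;
      for (size_t k = 0; k < offs.size(); ++k) {
        const double dist_term = offs[k].r2 / dta2;
        if (dist_term >= best) break;           // offsets sorted by r2
        // fractional pixel position of the probe point
        const double pi = i + offs[k].dx / spacing;
        const double pj = j + offs[k].dy / spacing;
        if (pi < 0.0 || pj < 0.0 || pi > nr - 1.0 || pj > nc - 1.0) continue;
        const int i0 = (int)std::floor(pi), j0 = (int)std::floor(pj);
        const int i1 = std::min(i0 + 1, nr - 1), j1 = std::min(j0 + 1, nc - 1);
        const double fi = pi - i0, fj = pj - j0;
        const double de =
          (1 - fi) * (1 - fj) * ev(i0, j0) + (1 - fi) * fj * ev(i0, j1) +
          fi * (1 - fj) * ev(i1, j0) + fi * fj * ev(i1, j1);
        const double dd = de - dref;
        double g2;
        if (tol > 0.0)
          g2 = (dd / tol) * (dd / tol) + dist_term;
        else
          g2 = (dd == 0.0) ? dist_term : R_PosInf;
        if (g2 < best) best = g2;
      }
      out(i, j) = std::sqrt(best);
    }
  }
  return out;
}
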