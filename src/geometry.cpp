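// Scattered-data geometry for fibre-bundle simulation: nearest-fibre
// (Voronoi) pixel assignment, Bowyer-Watson Delaunay triangulation and
// barycentric piecewise-linear interpolation. Pixel centers sit at integer
// (row, col) coordinates, 1-based, matching the R convention.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix cpp_nearest_map(NumericMatrix pos, int nrow, int ncol,
                              double cr, double cc, double radius) {
  const int n = pos.nrow();
  IntegerMatrix out(nrow, ncol);
  const double r2 = radius * radius;
  for (int c = 0; c < ncol; ++c) {
    for (int r = 0; r < nrow; ++r) {
      const double pr = r + 1.0, pc = c + 1.0;
      const double dr0 = pr - cr, dc0 = pc - cc;
      if (dr0 * dr0 + dc0 * dc0 > r2) {
        out(r, c) = NA_INTEGER;
        continue;
      }
      double best = std::numeric_limits<double>::infinity();
      int bi = 0;
      for (int i = 0; i < n; ++i) {
        const double dr = pr - pos(i, 0), dc = pc - pos(i, 1);
        const double d = dr * dr + dc * dc;
        if (d < best) { best = d; bi = i; }  // strict <: lowest index wins ties
      }
      out(r, c) = bi + 1;
    }
  }
  return out;
}

namespace {

struct Tri { int a, b, c; };

// robust-ish in-circumcircle predicate, long double accumulation;
// triangle (a,b,c) must be counter-clockwise
inline bool in_circle(const std::vector<long double>& px,
                      const std::vector<long double>& py,
                      int a, int b, int c, int d) {
  const long double adx = px[a] - px[d], ady = py[a] - py[d];
  const long double bdx = px[b] - px[d], bdy = py[b] - py[d];
  const long double cdx = px[c] - px[d], cdy = py[c] - py[d];
  const long double ad = adx * adx + ady * ady;
  const long double bd = bdx * bdx + bdy * bdy;
  const long double cd = cdx * cdx + cdy * cdy;
  const long double det = adx * (bdy * cd - bd * cdy)
                        - ady * (bdx * cd - bd * cdx)
                        + ad  * (bdx * cdy - bdy * cdx);
  return det > 0.0L;
}

inline long double orient2d(const std::vector<long double>& px,
                            const std::vector<long double>& py,
                            int a, int b, int c) {
  return (px[b] - px[a]) * (py[c] - py[a]) - (py[b] - py[a]) * (px[c] - px[a]);
}

}  // namespace

// Bowyer-Watson incremental Delaunay triangulation.
// pos: n x 2 (row, col). Returns m x 3 matrix of 1-based vertex indices.
// [[Rcpp::export]]
IntegerMatrix cpp_delaunay(NumericMatrix pos) {
  const int n = pos.nrow();
  if (n < 3) stop("need at least 3 points");
  std::vector<long double> px(n + 3), py(n + 3);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1);
    xmin = std::min(xmin, pos(i, 0)); xmax = std::max(xmax, pos(i, 0));
    ymin = std::min(ymin, pos(i, 1)); ymax = std::max(ymax, pos(i, 1));
  }
  const double dx = xmax - xmin, dy = ymax - ymin;
  const double dmax = std::max({dx, dy, 1.0});
  const double mx = (xmin + xmax) / 2.0, my = (ymin + ymax) / 2.0;
  // far-away super-triangle, acts as points at infinity
  const double big = 1e5 * dmax;
  px[n] = mx - big;     py[n] = my - big;
  px[n + 1] = mx + big; py[n + 1] = my - big;
  px[n + 2] = mx;       py[n + 2] = my + big;

  std::vector<Tri> tris;
  tris.reserve(4 * n);
  // super triangle oriented CCW in (x=row, y=col) plane
  {
    Tri t{n, n + 1, n + 2};
    if (orient2d(px, py, t.a, t.b, t.c) < 0) std::swap(t.b, t.c);
    tris.push_back(t);
  }
  std::vector<char> bad;
  std::vector<std::pair<int, int> > edges;
  for (int p = 0; p < n; ++p) {
    bad.assign(tris.size(), 0);
    edges.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      if (in_circle(px, py, tris[t].a, tris[t].b, tris[t].c, p)) bad[t] = 1;
    }
    // boundary of the cavity = edges appearing exactly once among bad triangles
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!bad[t]) continue;
      const int v[3] = {tris[t].a, tris[t].b, tris[t].c};
      for (int e = 0; e < 3; ++e) {
        edges.push_back(std::make_pair(v[e], v[(e + 1) % 3]));
      }
    }
    std::vector<char> dup(edges.size(), 0);
    for (size_t i = 0; i < edges.size(); ++i) {
      for (size_t j = i + 1; j < edges.size(); ++j) {
        if ((edges[i].first == edges[j].second && edges[i].second == edges[j].first) ||
            (edges[i].first == edges[j].first && edges[i].second == edges[j].second)) {
          dup[i] = dup[j] = 1;
        }
      }
    }
    std::vector<Tri> keep;
    keep.reserve(tris.size() + edges.size());
    for (size_t t = 0; t < tris.size(); ++t) if (!bad[t]) keep.push_back(tris[t]);
    for (size_t i = 0; i < edges.size(); ++i) {
      if (dup[i]) continue;
      Tri t{edges[i].first, edges[i].second, p};
      if (orient2d(px, py, t.a, t.b, t.c) < 0) std::swap(t.b, t.c);
      keep.push_back(t);
    }
    tris.swap(keep);
  }
  std::vector<Tri> final_tris;
  for (size_t t = 0; t < tris.size(); ++t) {
    if (tris[t].a < n && tris[t].b < n && tris[t].c < n) final_tris.push_back(tris[t]);
  }
  IntegerMatrix out(final_tris.size(), 3);
  for (size_t t = 0; t < final_tris.size(); ++t) {
    // sort vertices within the simplex for a canonical representation
    int v[3] = {final_tris[t].a, final_tris[t].b, final_tris[t].c};
    std::sort(v, v + 3);
    out(t, 0) = v[0] + 1; out(t, 1) = v[1] + 1; out(t, 2) = v[2] + 1;
  }
  return out;
}

// Piecewise-linear (barycentric) interpolation of per-fibre values onto the
// pixel grid. simplices are 1-based. In-FoV pixels outside the convex hull
// get the nearest fibre's value; out-of-FoV pixels stay 0.
// [[Rcpp::export]]
List cpp_interp_linear(NumericMatrix pos, IntegerMatrix simplices,
                       NumericVector values, int nrow, int ncol,
                       LogicalMatrix fov) {
  const int m = simplices.nrow();
  NumericMatrix out(nrow, ncol);
  LogicalMatrix in_hull(nrow, ncol);
  IntegerMatrix owner(nrow, ncol);
  std::fill(owner.begin(), owner.end(), 0);
  const double tol = 1e-9;
  for (int t = 0; t < m; ++t) {
    const int ia = simplices(t, 0) - 1, ib = simplices(t, 1) - 1, ic = simplices(t, 2) - 1;
    const double ar = pos(ia, 0), ac = pos(ia, 1);
    const double br = pos(ib, 0), bc = pos(ib, 1);
    const double cr = pos(ic, 0), cc = pos(ic, 1);
    const double det = (br - ar) * (cc - ac) - (cr - ar) * (bc - ac);
    if (det == 0.0) continue;
    const int r0 = std::max(0, (int)std::ceil(std::min({ar, br, cr})) - 1);
    const int r1 = std::min(nrow - 1, (int)std::floor(std::max({ar, br, cr})) - 1 + 1);
    const int c0 = std::max(0, (int)std::ceil(std::min({ac, bc, cc})) - 1);
    const int c1 = std::min(ncol - 1, (int)std::floor(std::max({ac, bc, cc})) - 1 + 1);
    for (int c = c0; c <= c1; ++c) {
      for (int r = r0; r <= r1; ++r) {
        if (owner(r, c) || !fov(r, c)) continue;
        const double prr = r + 1.0, pcc = c + 1.0;
        const double l1 = ((prr - ar) * (cc - ac) - (cr - ar) * (pcc - ac)) / det;
        const double l2 = ((br - ar) * (pcc - ac) - (prr - ar) * (bc - ac)) / det;
        const double l0 = 1.0 - l1 - l2;
        if (l0 >= -tol && l1 >= -tol && l2 >= -tol) {
          owner(r, c) = t + 1;  // triangles scanned in index order: lowest wins
          in_hull(r, c) = true;
          out(r, c) = l0 * values[ia] + l1 * values[ib] + l2 * values[ic];
        }
      }
    }
  }
  // nearest-fibre fill for in-FoV pixels outside the hull
  const int n = pos.nrow();
  for (int c = 0; c < ncol; ++c) {
    for (int r = 0; r < nrow; ++r) {
      if (!fov(r, c) || owner(r, c)) continue;
      const double prr = r + 1.0, pcc = c + 1.0;
      double best = std::numeric_limits<double>::infinity();
      int bi = 0;
      for (int i = 0; i < n; ++i) {
        const double dr = prr - pos(i, 0), dc = pcc - pos(i, 1);
        const double d = dr * dr + dc * dc;
        if (d < best) { best = d; bi = i; }
      }
      out(r, c) = values[bi];
      in_hull(r, c) = false;
    }
  }
  return List::create(_["pixels"] = out, _["in_hull"] = in_hull);
}

// Mean of the k pixel values nearest to each fibre position (Euclidean
// distance between fibre position and pixel centers; ties broken by the
// lower row-major pixel index).
// [[Rcpp::export]]
NumericVector cpp_knn_mean(NumericMatrix pos, NumericMatrix img, int k) {
  const int n = pos.nrow(), nrow = img.nrow(), ncol = img.ncol();
  if (k < 1 || k > nrow * ncol) stop("k out of range");
  NumericVector out(n);
  struct Cand { double d2; long idx; double val; };
  std::vector<Cand> cand;
  for (int i = 0; i < n; ++i) {
    const double fr = pos(i, 0), fc = pos(i, 1);
    int h = (int)std::ceil(std::sqrt((double)k)) + 1;
    for (;; ++h) {
      cand.clear();
      const int r0 = std::max(1, (int)std::floor(fr) - h);
      const int r1 = std::min(nrow, (int)std::ceil(fr) + h);
      const int c0 = std::max(1, (int)std::floor(fc) - h);
      const int c1 = std::min(ncol, (int)std::ceil(fc) + h);
      for (int r = r0; r <= r1; ++r) {
        for (int c = c0; c <= c1; ++c) {
          const double dr = r - fr, dc = c - fc;
          cand.push_back(Cand{dr * dr + dc * dc,
                              (long)(r - 1) * ncol + (c - 1), img(r - 1, c - 1)});
        }
      }
      if ((int)cand.size() < k) {
        if (r0 == 1 && c0 == 1 && r1 == nrow && c1 == ncol) stop("k too large");
        continue;
      }
      std::sort(cand.begin(), cand.end(), [](const Cand& a, const Cand& b) {
        return a.d2 < b.d2 || (a.d2 == b.d2 && a.idx < b.idx);
      });
      const bool window_clipped = (r0 == 1 && c0 == 1 && r1 == nrow && c1 == ncol);
      // safe when the kth distance cannot be beaten by a pixel outside the window
      const double hmin = std::min({fr - r0, fc - c0, (double)r1 - fr, (double)c1 - fc});
      if (window_clipped || cand[k - 1].d2 <= hmin * hmin) break;
    }
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += cand[j].val;
    out[i] = s / k;
  }
  return out;
}
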