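// Volume of the 3D convex hull of a point cloud, by incremental insertion.
// Exact enough for polymer conformations (coordinates O(10), n O(10^3));
// degenerate (coplanar) inputs are rejected.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdlib>

using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
};
static inline V3 sub(const V3 &a, const V3 &b) {
  V3 r = {a.x - b.x, a.y - b.y, a.z - b.z};
  return r;
}
static inline V3 cross(const V3 &a, const V3 &b) {
  V3 r = {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
  return r;
}
static inline double dot(const V3 &a, const V3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

struct Face {
  int a, b, c;
  V3 normal;   // outward
  double off;  // dot(normal, vertex a)
  bool alive;
};

}  // namespace

// [[Rcpp::export(name = ".cpp_hull_volume")]]
double cpp_hull_volume(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("convex hull volume needs at least 4 points");
  std::vector<V3> p(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    p[i].x = pts(i, 0); p[i].y = pts(i, 1); p[i].z = pts(i, 2);
    scale = std::max(scale, std::fabs(p[i].x));
    scale = std::max(scale, std::fabs(p[i].y));
    scale = std::max(scale, std::fabs(p[i].z));
  }
  if (scale == 0.0) scale = 1.0;
  double eps = 1e-10 * scale * scale * scale + 1e-300;

  // initial simplex: two most distant of a probe set, then max-area, max-vol
  int i0 = 0, i1 = 1;
  double best = -1.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      V3 d = sub(p[i], p[j]);
      double l = dot(d, d);
      if (l > best) { best = l; i0 = i; i1 = j; }
    }
  if (best <= 0.0) stop("degenerate input: all points coincide");
  int i2 = -1;
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    V3 c = cross(sub(p[i1], p[i0]), sub(p[i], p[i0]));
    double a = dot(c, c);
    if (a > best) { best = a; i2 = i; }
  }
  if (i2 < 0 || best <= eps * eps) stop("degenerate input: points are collinear");
  int i3 = -1;
  best = -1.0;
  V3 nrm = cross(sub(p[i1], p[i0]), sub(p[i2], p[i0]));
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2) continue;
    double v = std::fabs(dot(nrm, sub(p[i], p[i0])));
    if (v > best) { best = v; i3 = i; }
  }
  if (i3 < 0 || best <= eps) stop("degenerate input: points are coplanar");

  V3 interior = {(p[i0].x + p[i1].x + p[i2].x + p[i3].x) / 4.0,
                 (p[i0].y + p[i1].y + p[i2].y + p[i3].y) / 4.0,
                 (p[i0].z + p[i1].z + p[i2].z + p[i3].z) / 4.0};

  std::vector<Face> faces;
  int tet[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
  for (int f = 0; f < 4; ++f) {
    Face fc;
    fc.a = tet[f][0]; fc.b = tet[f][1]; fc.c = tet[f][2];
    fc.normal = cross(sub(p[fc.b], p[fc.a]), sub(p[fc.c], p[fc.a]));
    fc.off = dot(fc.normal, p[fc.a]);
    if (dot(fc.normal, interior) > fc.off) {  // flip to point outward
      std::swap(fc.b, fc.c);
      fc.normal.x = -fc.normal.x; fc.normal.y = -fc.normal.y;
      fc.normal.z = -fc.normal.z;
      fc.off = -fc.off;
    }
    fc.alive = true;
    faces.push_back(fc);
  }

  for (int q = 0; q < n; ++q) {
    if (q == i0 || q == i1 || q == i2 || q == i3) continue;
    std::vector<int> visible;
    for (size_t f = 0; f < faces.size(); ++f)
      if (faces[f].alive && dot(faces[f].normal, p[q]) - faces[f].off > eps)
        visible.push_back(static_cast<int>(f));
    if (visible.empty()) continue;
    // horizon = directed edges of visible faces whose reverse is not visible
    std::vector<std::pair<int, int> > edges;
    for (size_t vi = 0; vi < visible.size(); ++vi) {
      const Face &fc = faces[visible[vi]];
      int e[3][2] = {{fc.a, fc.b}, {fc.b, fc.c}, {fc.c, fc.a}};
      for (int k = 0; k < 3; ++k) edges.push_back(std::make_pair(e[k][0], e[k][1]));
    }
    std::vector<std::pair<int, int> > horizon;
    for (size_t e = 0; e < edges.size(); ++e) {
      bool twin = false;
      for (size_t g = 0; g < edges.size(); ++g)
        if (edges[g].first == edges[e].second &&
            edges[g].second == edges[e].first) { twin = true; break; }
      if (!twin) horizon.push_back(edges[e]);
    }
    for (size_t vi = 0; vi < visible.size(); ++vi) faces[visible[vi]].alive = false;
    for (size_t h = 0; h < horizon.size(); ++h) {
      Face fc;
      fc.a = horizon[h].first; fc.b = horizon[h].second; fc.c = q;
      fc.normal = cross(sub(p[fc.b], p[fc.a]), sub(p[fc.c], p[fc.a]));
      fc.off = dot(fc.normal, p[fc.a]);
      if (dot(fc.normal, interior) > fc.off) {
        std::swap(fc.b, fc.c);
        fc.normal.x = -fc.normal.x; fc.normal.y = -fc.normal.y;
        fc.normal.z = -fc.normal.z;
        fc.off = -fc.off;
      }
      fc.alive = true;
      faces.push_back(fc);
    }
  }

  double vol = 0.0;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    V3 a = sub(p[faces[f].a], interior), b = sub(p[faces[f].b], interior),
       c = sub(p[faces[f].c], interior);
    vol += dot(a, cross(b, c)) / 6.0;
  }
  return std::fabs(vol);
}
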