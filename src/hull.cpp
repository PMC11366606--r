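// 3D convex hull by the quickhull algorithm. Returns outward-oriented
// triangular facets plus enclosed volume and facet area.
#include <Rcpp.h>
#include <cmath>
#include <map>
#include <utility>
#include <vector>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};
inline Vec3 vsub(const Vec3& a, const Vec3& b) {
  Vec3 r = {a.x - b.x, a.y - b.y, a.z - b.z};
  return r;
}
inline Vec3 vcross(const Vec3& a, const Vec3& b) {
  Vec3 r = {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
  return r;
}
inline double vdot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double vnorm(const Vec3& a) { return std::sqrt(vdot(a, a)); }

struct Face {
  int a, b, c;
  Vec3 n;        // outward unit normal
  double off;    // n . x = off on the plane
  bool alive;
  std::vector<int> outside;
  int far_idx;
  double far_d;
};

double plane_dist(const Face& f, const Vec3& p) { return vdot(f.n, p) - f.off; }

void face_plane(Face& f, const std::vector<Vec3>& P, const Vec3& interior) {
  Vec3 n = vcross(vsub(P[f.b], P[f.a]), vsub(P[f.c], P[f.a]));
  double nn = vnorm(n);
  if (nn > 0) { n.x /= nn; n.y /= nn; n.z /= nn; }
  double off = vdot(n, P[f.a]);
  if (vdot(n, interior) - off > 0) {  // flip to point away from interior
    std::swap(f.b, f.c);
    n.x = -n.x; n.y = -n.y; n.z = -n.z;
    off = -off;
  }
  f.n = n;
  f.off = off;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_quickhull")]]
List cpp_quickhull(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");
  std::vector<Vec3> P(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    P[i].x = pts(i, 0); P[i].y = pts(i, 1); P[i].z = pts(i, 2);
    scale = std::max(scale, std::fabs(P[i].x));
    scale = std::max(scale, std::fabs(P[i].y));
    scale = std::max(scale, std::fabs(P[i].z));
  }
  double eps = 1e-12 * (scale > 0 ? scale : 1.0) * 10.0;

  // initial simplex: extremes in x, farthest from line, farthest from plane
  int i0 = 0, i1 = 0;
  for (int i = 1; i < n; ++i) {
    if (P[i].x < P[i0].x) i0 = i;
    if (P[i].x > P[i1].x) i1 = i;
  }
  if (i0 == i1) { i1 = (i0 + 1) % n; }
  int i2 = -1;
  double best = eps;
  Vec3 d01 = vsub(P[i1], P[i0]);
  double l01 = vnorm(d01);
  if (l01 == 0) stop("degenerate input: coincident points");
  for (int i = 0; i < n; ++i) {
    double d = vnorm(vcross(d01, vsub(P[i], P[i0]))) / l01;
    if (d > best) { best = d; i2 = i; }
  }
  if (i2 < 0) stop("degenerate input: points are collinear");
  int i3 = -1;
  Vec3 n012 = vcross(d01, vsub(P[i2], P[i0]));
  double nn = vnorm(n012);
  n012.x /= nn; n012.y /= nn; n012.z /= nn;
  best = eps;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(vdot(n012, vsub(P[i], P[i0])));
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) stop("degenerate input: points are coplanar");

  Vec3 interior = {(P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0,
                   (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0,
                   (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0};

  std::vector<Face> faces;
  int tet[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
  for (int f = 0; f < 4; ++f) {
    Face fc;
    fc.a = tet[f][0]; fc.b = tet[f][1]; fc.c = tet[f][2];
    fc.alive = true; fc.far_idx = -1; fc.far_d = 0;
    face_plane(fc, P, interior);
    faces.push_back(fc);
  }
  // distribute points to outside sets
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    for (size_t f = 0; f < faces.size(); ++f) {
      double d = plane_dist(faces[f], P[i]);
      if (d > eps) {
        faces[f].outside.push_back(i);
        if (d > faces[f].far_d) { faces[f].far_d = d; faces[f].far_idx = i; }
        break;
      }
    }
  }

  bool progressed = true;
  while (progressed) {
    progressed = false;
    for (size_t f0 = 0; f0 < faces.size(); ++f0) {
      if (!faces[f0].alive || faces[f0].far_idx < 0) continue;
      progressed = true;
      int p = faces[f0].far_idx;
      // visible faces
      std::vector<int> visible;
      for (size_t f = 0; f < faces.size(); ++f) {
        if (faces[f].alive && plane_dist(faces[f], P[p]) > eps)
          visible.push_back((int)f);
      }
      // horizon = undirected edges used by exactly one visible face
      std::map<std::pair<int, int>, std::pair<int, int> > edges;  // key -> (count, oriented a)
      for (size_t v = 0; v < visible.size(); ++v) {
        const Face& fc = faces[visible[v]];
        int vv[3] = {fc.a, fc.b, fc.c};
        for (int e = 0; e < 3; ++e) {
          int a = vv[e], b = vv[(e + 1) % 3];
          std::pair<int, int> key = a < b ? std::make_pair(a, b) : std::make_pair(b, a);
          std::map<std::pair<int, int>, std::pair<int, int> >::iterator it = edges.find(key);
          if (it == edges.end()) edges[key] = std::make_pair(1, a);
          else it->second.first += 1;
        }
      }
      // collect orphaned outside points, kill visible faces
      std::vector<int> orphans;
      for (size_t v = 0; v < visible.size(); ++v) {
        Face& fc = faces[visible[v]];
        for (size_t j = 0; j < fc.outside.size(); ++j)
          if (fc.outside[j] != p) orphans.push_back(fc.outside[j]);
        fc.alive = false;
        fc.outside.clear();
        fc.far_idx = -1;
      }
      // new faces from horizon edges to p
      std::vector<int> created;
      for (std::map<std::pair<int, int>, std::pair<int, int> >::iterator it = edges.begin();
           it != edges.end(); ++it) {
        if (it->second.first != 1) continue;
        Face fc;
        fc.a = it->first.first; fc.b = it->first.second; fc.c = p;
        fc.alive = true; fc.far_idx = -1; fc.far_d = 0;
        face_plane(fc, P, interior);
        faces.push_back(fc);
        created.push_back((int)faces.size() - 1);
      }
      for (size_t j = 0; j < orphans.size(); ++j) {
        int q = orphans[j];
        for (size_t c = 0; c < created.size(); ++c) {
          Face& fc = faces[created[c]];
          double d = plane_dist(fc, P[q]);
          if (d > eps) {
            fc.outside.push_back(q);
            if (d > fc.far_d) { fc.far_d = d; fc.far_idx = q; }
            break;
          }
        }
      }
      break;  // restart scan (faces vector changed)
    }
  }

  int nf = 0;
  for (size_t f = 0; f < faces.size(); ++f)
    if (faces[f].alive) ++nf;
  IntegerMatrix F(nf, 3);
  double vol = 0.0, area = 0.0;
  int r = 0;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    const Face& fc = faces[f];
    F(r, 0) = fc.a + 1; F(r, 1) = fc.b + 1; F(r, 2) = fc.c + 1;
    ++r;
    Vec3 pa = vsub(P[fc.a], interior), pb = vsub(P[fc.b], interior),
         pc = vsub(P[fc.c], interior);
    vol += vdot(pa, vcross(pb, pc)) / 6.0;
    area += vnorm(vcross(vsub(P[fc.b], P[fc.a]), vsub(P[fc.c], P[fc.a]))) / 2.0;
  }
  return List::create(_["faces"] = F, _["volume"] = vol, _["area"] = area);
}
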