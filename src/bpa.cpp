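// Ball-pivoting surface reconstruction: a ball of radius r is seated on three
// points and pivoted around front edges; every rest position spans a triangle.
// Multi-radius passes reuse the mesh and retry boundary edges with larger balls.
// Requires consistently oriented per-vertex normals (ball centers are placed on
// the normal side of each triangle).
#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <cstdint>
#include <deque>
#include <map>
#include <set>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
};
inline V3 operator-(const V3& a, const V3& b) { return V3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline V3 operator+(const V3& a, const V3& b) { return V3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline V3 operator*(const V3& a, double s) { return V3(a.x * s, a.y * s, a.z * s); }
inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

struct Grid {
  double cell;
  double minc[3];
  std::unordered_map<int64_t, std::vector<int> > cells;

  static int64_t key(int ix, int iy, int iz) {
    return ((int64_t)(ix + 4) << 42) | ((int64_t)(iy + 4) << 21) | (int64_t)(iz + 4);
  }
  void build(const std::vector<V3>& P, double cell_) {
    cell = cell_;
    cells.clear();
    minc[0] = minc[1] = minc[2] = 0;
    if (P.empty()) return;
    minc[0] = P[0].x; minc[1] = P[0].y; minc[2] = P[0].z;
    for (size_t i = 1; i < P.size(); ++i) {
      minc[0] = std::min(minc[0], P[i].x);
      minc[1] = std::min(minc[1], P[i].y);
      minc[2] = std::min(minc[2], P[i].z);
    }
    for (size_t i = 0; i < P.size(); ++i) {
      cells[key(ix(P[i].x, 0), ix(P[i].y, 1), ix(P[i].z, 2))].push_back((int)i);
    }
  }
  int ix(double v, int a) const { return (int)std::floor((v - minc[a]) / cell); }
  // all points within `rad` (<= cell) of q
  void query(const std::vector<V3>& P, const V3& q, double rad, std::vector<int>& out) const {
    out.clear();
    double r2 = rad * rad;
    int qx = ix(q.x, 0), qy = ix(q.y, 1), qz = ix(q.z, 2);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          std::unordered_map<int64_t, std::vector<int> >::const_iterator it =
              cells.find(key(qx + dx, qy + dy, qz + dz));
          if (it == cells.end()) continue;
          for (size_t j = 0; j < it->second.size(); ++j) {
            int p = it->second[j];
            V3 d = P[p] - q;
            if (dot(d, d) <= r2) out.push_back(p);
          }
        }
  }
};

struct EdgeInfo {
  int count;    // adjacent faces so far
  int state;    // 1 front, 2 inner, 3 boundary
  int opp;      // opposite vertex of the (first) adjacent face
  V3 center;    // ball center of that face
};

struct BPA {
  std::vector<V3> P, N;
  double r;
  Grid grid;
  std::vector<std::array<int, 3> > faces;
  std::set<std::array<int, 3> > face_set;
  std::map<std::pair<int, int>, EdgeInfo> edges;
  std::deque<std::pair<int, int> > front;
  std::vector<char> used;

  static std::pair<int, int> ekey(int a, int b) {
    return a < b ? std::make_pair(a, b) : std::make_pair(b, a);
  }

  // ball center touching a,b,c with radius r, on the normal-consistent side;
  // returns false if the circumradius exceeds r or the triangle is degenerate
  bool ball_center(int a, int b, int c, V3& out) const {
    V3 A = P[a], AB = P[b] - P[a], AC = P[c] - P[a];
    V3 n = cross(AB, AC);
    double n2 = dot(n, n);
    if (n2 < 1e-30) return false;
    V3 cc = A + (cross(n, AB) * dot(AC, AC) + cross(AC, n) * dot(AB, AB)) * (0.5 / n2);
    double rc2 = dot(cc - A, cc - A);
    double h2 = r * r - rc2;
    if (h2 <= 0) return false;
    double nn = std::sqrt(n2);
    V3 nh = n * (1.0 / nn);
    V3 avg = N[a] + N[b] + N[c];
    if (dot(nh, avg) < 0) nh = nh * (-1.0);
    out = cc + nh * std::sqrt(h2);
    return true;
  }

  bool ball_empty(const V3& c, int a, int b, int x, std::vector<int>& buf) const {
    grid.query(P, c, r, buf);
    double lim = r * r * (1.0 - 1e-7);
    for (size_t j = 0; j < buf.size(); ++j) {
      int q = buf[j];
      if (q == a || q == b || q == x) continue;
      V3 d = P[q] - c;
      if (dot(d, d) < lim) return false;
    }
    return true;
  }

  bool can_add(int a, int b, int c) const {
    std::array<int, 3> t = {{a, b, c}};
    std::sort(t.begin(), t.end());
    if (face_set.count(t)) return false;
    int e[3][2] = {{a, b}, {b, c}, {a, c}};
    for (int i = 0; i < 3; ++i) {
      std::map<std::pair<int, int>, EdgeInfo>::const_iterator it =
          edges.find(ekey(e[i][0], e[i][1]));
      if (it != edges.end() && it->second.count >= 2) return false;
    }
    return true;
  }

  void add_face(int a, int b, int c, const V3& center) {
    std::array<int, 3> t = {{a, b, c}};
    std::array<int, 3> ts = t;
    std::sort(ts.begin(), ts.end());
    face_set.insert(ts);
    faces.push_back(t);
    used[a] = used[b] = used[c] = 1;
    int e[3][3] = {{a, b, c}, {b, c, a}, {a, c, b}};
    for (int i = 0; i < 3; ++i) {
      std::pair<int, int> k = ekey(e[i][0], e[i][1]);
      std::map<std::pair<int, int>, EdgeInfo>::iterator it = edges.find(k);
      if (it == edges.end()) {
        EdgeInfo inf;
        inf.count = 1;
        inf.state = 1;
        inf.opp = e[i][2];
        inf.center = center;
        edges[k] = inf;
        front.push_back(k);
      } else {
        it->second.count += 1;
        it->second.state = 2;  // two faces -> interior edge
      }
    }
  }

  void pivot(const std::pair<int, int>& k) {
    std::map<std::pair<int, int>, EdgeInfo>::iterator it = edges.find(k);
    if (it == edges.end() || it->second.state != 1) return;
    int a = k.first, b = k.second, o = it->second.opp;
    V3 m = (P[a] + P[b]) * 0.5;
    V3 e = P[b] - P[a];
    double el = norm(e);
    if (el < 1e-30) { it->second.state = 3; return; }
    e = e * (1.0 / el);
    V3 u = it->second.center - m;
    double ul = norm(u);
    if (ul < 1e-30) { it->second.state = 3; return; }
    u = u * (1.0 / ul);
    V3 v = cross(e, u);
    if (dot(v, P[o] - m) > 0) v = v * (-1.0);

    std::vector<int> cand, buf;
    grid.query(P, m, 2.0 * r, cand);
    double best_theta = 1e30;
    int best_x = -1;
    V3 best_c;
    for (size_t j = 0; j < cand.size(); ++j) {
      int x = cand[j];
      if (x == a || x == b || x == o) continue;
      V3 cx;
      if (!ball_center(a, b, x, cx)) continue;
      V3 d = cx - m;
      double th = std::atan2(dot(d, v), dot(d, u));
      if (th < 1e-9) th += 2.0 * M_PI;
      if (th < best_theta && can_add(a, b, x)) {
        // accept the first (smallest rotation) candidate whose ball is empty
        if (ball_empty(cx, a, b, x, buf)) {
          best_theta = th;
          best_x = x;
          best_c = cx;
        }
      }
    }
    if (best_x >= 0) {
      it->second.count += 1;
      it->second.state = 2;
      add_face(a, b, best_x, best_c);
    } else {
      it->second.state = 3;  // boundary for this radius
    }
  }

  bool find_seed() {
    std::vector<int> nb, buf;
    int n = (int)P.size();
    for (int a = 0; a < n; ++a) {
      if (used[a]) continue;
      grid.query(P, a < 0 ? V3() : P[a], 2.0 * r, nb);
      // sort neighbours by distance to a
      std::vector<std::pair<double, int> > ds;
      for (size_t j = 0; j < nb.size(); ++j) {
        if (nb[j] == a || used[nb[j]]) continue;
        V3 d = P[nb[j]] - P[a];
        ds.push_back(std::make_pair(dot(d, d), nb[j]));
      }
      std::sort(ds.begin(), ds.end());
      int lim = std::min((int)ds.size(), 24);
      for (int j = 0; j < lim; ++j) {
        for (int l = j + 1; l < lim; ++l) {
          int b = ds[j].second, x = ds[l].second;
          V3 c;
          if (!ball_center(a, b, x, c)) continue;
          if (!ball_empty(c, a, b, x, buf)) continue;
          if (!can_add(a, b, x)) continue;
          add_face(a, b, x, c);
          return true;
        }
      }
    }
    return false;
  }

  void run_radius(double r_) {
    r = r_;
    grid.build(P, 2.0 * r);
    // retry boundary edges with the larger ball
    std::vector<std::pair<int, int> > retry;
    for (std::map<std::pair<int, int>, EdgeInfo>::iterator it = edges.begin();
         it != edges.end(); ++it) {
      if (it->second.state == 3 && it->second.count == 1) retry.push_back(it->first);
    }
    for (size_t i = 0; i < retry.size(); ++i) {
      EdgeInfo& inf = edges[retry[i]];
      V3 c;
      if (ball_center(retry[i].first, retry[i].second, inf.opp, c)) {
        inf.center = c;
        inf.state = 1;
        front.push_back(retry[i]);
      }
    }
    while (true) {
      while (!front.empty()) {
        std::pair<int, int> k = front.front();
        front.pop_front();
        pivot(k);
      }
      if (!find_seed()) break;
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_ball_pivot")]]
IntegerMatrix cpp_ball_pivot(NumericMatrix pts, NumericMatrix normals,
                             NumericVector radii) {
  int n = pts.nrow();
  if (normals.nrow() != n) stop("normals must match points");
  BPA bpa;
  bpa.P.resize(n);
  bpa.N.resize(n);
  for (int i = 0; i < n; ++i) {
    bpa.P[i] = V3(pts(i, 0), pts(i, 1), pts(i, 2));
    bpa.N[i] = V3(normals(i, 0), normals(i, 1), normals(i, 2));
  }
  bpa.used.assign(n, 0);
  NumericVector r = clone(radii);
  std::sort(r.begin(), r.end());
  for (int j = 0; j < r.size(); ++j) {
    if (r[j] <= 0) stop("radii must be > 0");
    bpa.run_radius(r[j]);
  }
  IntegerMatrix F((int)bpa.faces.size(), 3);
  for (size_t i = 0; i < bpa.faces.size(); ++i) {
    F((int)i, 0) = bpa.faces[i][0] + 1;
    F((int)i, 1) = bpa.faces[i][1] + 1;
    F((int)i, 2) = bpa.faces[i][2] + 1;
  }
  return F;
}
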