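// kd-tree nearest-neighbour search and PCA local geometry for 3D point clouds.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>
using namespace Rcpp;

namespace {

class KDTree3 {
public:
  KDTree3(const NumericMatrix& P) : P_(P), n_(P.nrow()), idx_(P.nrow()) {
    for (int i = 0; i < n_; ++i) idx_[i] = i;
    if (n_ > 0) build(0, n_, 0);
  }

  // k nearest neighbours of query q; `exclude` (point index) skipped, -1 for none.
  void knn(const double* q, int k, int exclude,
           std::vector<int>& out_idx, std::vector<double>& out_d2) const {
    std::priority_queue<std::pair<double, int> > pq;  // max-heap on d2
    search(0, n_, 0, q, k, exclude, pq);
    int m = (int)pq.size();
    out_idx.assign(m, -1);
    out_d2.assign(m, 0.0);
    for (int j = m - 1; j >= 0; --j) {
      out_d2[j] = pq.top().first;
      out_idx[j] = pq.top().second;
      pq.pop();
    }
  }

private:
  const NumericMatrix& P_;
  int n_;
  std::vector<int> idx_;

  double coord(int p, int ax) const { return P_(p, ax); }

  void build(int lo, int hi, int ax) {
    if (hi - lo <= 1) return;
    int mid = (lo + hi) / 2;
    const NumericMatrix& P = P_;
    std::nth_element(idx_.begin() + lo, idx_.begin() + mid, idx_.begin() + hi,
                     [&P, ax](int a, int b) { return P(a, ax) < P(b, ax); });
    build(lo, mid, (ax + 1) % 3);
    build(mid + 1, hi, (ax + 1) % 3);
  }

  double dist2(const double* q, int p) const {
    double dx = q[0] - P_(p, 0), dy = q[1] - P_(p, 1), dz = q[2] - P_(p, 2);
    return dx * dx + dy * dy + dz * dz;
  }

  void search(int lo, int hi, int ax, const double* q, int k, int exclude,
              std::priority_queue<std::pair<double, int> >& pq) const {
    if (hi <= lo) return;
    int mid = (lo + hi) / 2;
    int p = idx_[mid];
    if (p != exclude) {
      double d2 = dist2(q, p);
      if ((int)pq.size() < k) pq.push(std::make_pair(d2, p));
      else if (d2 < pq.top().first) { pq.pop(); pq.push(std::make_pair(d2, p)); }
    }
    double diff = q[ax] - coord(p, ax);
    int nax = (ax + 1) % 3;
    if (diff < 0) {
      search(lo, mid, nax, q, k, exclude, pq);
      if ((int)pq.size() < k || diff * diff <= pq.top().first)
        search(mid + 1, hi, nax, q, k, exclude, pq);
    } else {
      search(mid + 1, hi, nax, q, k, exclude, pq);
      if ((int)pq.size() < k || diff * diff <= pq.top().first)
        search(lo, mid, nax, q, k, exclude, pq);
    }
  }
};

// Eigen-decomposition of a symmetric 3x3 matrix by cyclic Jacobi rotations.
// Ascending eigenvalues; columns of V are the matching eigenvectors.
void eigen_sym3(double a[3][3], double eval[3], double evec[3][3]) {
  double v[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = std::fabs(a[0][1]) + std::fabs(a[0][2]) + std::fabs(a[1][2]);
    if (off < 1e-300) break;
    double diag = std::fabs(a[0][0]) + std::fabs(a[1][1]) + std::fabs(a[2][2]);
    if (off <= 1e-15 * (diag > 0 ? diag : 1.0)) break;
    for (int p = 0; p < 2; ++p) {
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(a[p][q]) < 1e-300) continue;
        double theta = (a[q][q] - a[p][p]) / (2.0 * a[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int r = 0; r < 3; ++r) {
          double arp = a[r][p], arq = a[r][q];
          a[r][p] = c * arp - s * arq;
          a[r][q] = s * arp + c * arq;
        }
        for (int r = 0; r < 3; ++r) {
          double apr = a[p][r], aqr = a[q][r];
          a[p][r] = c * apr - s * aqr;
          a[q][r] = s * apr + c * aqr;
        }
        for (int r = 0; r < 3; ++r) {
          double vrp = v[r][p], vrq = v[r][q];
          v[r][p] = c * vrp - s * vrq;
          v[r][q] = s * vrp + c * vrq;
        }
      }
    }
  }
  int ord[3] = {0, 1, 2};
  double d[3] = {a[0][0], a[1][1], a[2][2]};
  for (int i = 0; i < 2; ++i)
    for (int j = i + 1; j < 3; ++j)
      if (d[ord[j]] < d[ord[i]]) std::swap(ord[i], ord[j]);
  for (int i = 0; i < 3; ++i) {
    eval[i] = d[ord[i]];
    for (int r = 0; r < 3; ++r) evec[r][i] = v[r][ord[i]];
  }
}

}  // namespace

// [[Rcpp::export(name = ".cpp_knn")]]
List cpp_knn(NumericMatrix pts, int k, bool exclude_self = true) {
  int n = pts.nrow();
  if (k < 1) stop("k must be >= 1");
  if (exclude_self && n <= k) stop("need more points than k");
  KDTree3 tree(pts);
  IntegerMatrix idx(n, k);
  NumericMatrix dist(n, k);
  std::vector<int> ii;
  std::vector<double> dd;
  double q[3];
  for (int i = 0; i < n; ++i) {
    q[0] = pts(i, 0); q[1] = pts(i, 1); q[2] = pts(i, 2);
    tree.knn(q, k, exclude_self ? i : -1, ii, dd);
    int m = (int)ii.size();
    for (int j = 0; j < k; ++j) {
      idx(i, j) = j < m ? ii[j] + 1 : NA_INTEGER;
      dist(i, j) = j < m ? std::sqrt(dd[j]) : NA_REAL;
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Per-point PCA of the k-NN neighbourhood (point included): unit normal from
// the smallest-eigenvalue eigenvector and surface variation
// lambda0 / (lambda0 + lambda1 + lambda2).
// [[Rcpp::export(name = ".cpp_local_geometry")]]
List cpp_local_geometry(NumericMatrix pts, int k) {
  int n = pts.nrow();
  if (k < 3) stop("k must be >= 3");
  if (n <= k) stop("need more points than k");
  KDTree3 tree(pts);
  NumericMatrix normals(n, 3);
  NumericVector curv(n);
  std::vector<int> ii;
  std::vector<double> dd;
  double q[3];
  for (int i = 0; i < n; ++i) {
    q[0] = pts(i, 0); q[1] = pts(i, 1); q[2] = pts(i, 2);
    tree.knn(q, k, i, ii, dd);
    int m = (int)ii.size() + 1;
    double mx = q[0], my = q[1], mz = q[2];
    for (size_t j = 0; j < ii.size(); ++j) {
      mx += pts(ii[j], 0); my += pts(ii[j], 1); mz += pts(ii[j], 2);
    }
    mx /= m; my /= m; mz /= m;
    double C[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int j = -1; j < (int)ii.size(); ++j) {
      int p = j < 0 ? i : ii[j];
      double dx = pts(p, 0) - mx, dy = pts(p, 1) - my, dz = pts(p, 2) - mz;
      C[0][0] += dx * dx; C[0][1] += dx * dy; C[0][2] += dx * dz;
      C[1][1] += dy * dy; C[1][2] += dy * dz; C[2][2] += dz * dz;
    }
    C[1][0] = C[0][1]; C[2][0] = C[0][2]; C[2][1] = C[1][2];
    double eval[3], evec[3][3];
    eigen_sym3(C, eval, evec);
    double tot = eval[0] + eval[1] + eval[2];
    curv[i] = tot > 0 ? std::max(0.0, eval[0]) / tot : 0.0;
    double nx = evec[0][0], ny = evec[1][0], nz = evec[2][0];
    // sign: prefer +z hemisphere, then +x, then +y
    double s = nz != 0 ? nz : (nx != 0 ? nx : ny);
    if (s < 0) { nx = -nx; ny = -ny; nz = -nz; }
    double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
    if (nn == 0) { nx = 0; ny = 0; nz = 1; nn = 1; }
    normals(i, 0) = nx / nn; normals(i, 1) = ny / nn; normals(i, 2) = nz / nn;
  }
  return List::create(_["normals"] = normals, _["curvature"] = curv);
}
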