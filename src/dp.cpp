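// Elastic matching kernels: segment edge costs and the monotone
// dynamic-programming search over the n x n matching graph.
//
// The matching graph is a DAG (vertices (i, j) on the common grid, edges
// strictly increasing in both indices with jump window w), so a single
// topological-order pass attains the all-pairs-shortest-path optimum.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Linear interpolation of the (dim x n) column-curve Q at parameter t.
static inline void interp_col(const NumericMatrix &Q, const NumericVector &T,
                              double t, std::vector<double> &out) {
  const int n = T.size(), dim = Q.nrow();
  if (t <= T[0]) {
    for (int d = 0; d < dim; ++d) out[d] = Q(d, 0);
    return;
  }
  if (t >= T[n - 1]) {
    for (int d = 0; d < dim; ++d) out[d] = Q(d, n - 1);
    return;
  }
  int lo = int(std::upper_bound(T.begin(), T.end(), t) - T.begin()) - 1;
  if (lo > n - 2) lo = n - 2;
  const double w = (t - T[lo]) / (T[lo + 1] - T[lo]);
  for (int d = 0; d < dim; ++d)
    out[d] = (1.0 - w) * Q(d, lo) + w * Q(d, lo + 1);
}

// Squared-L2 elastic cost of matching grid segment [T_i, T_ip] of Q1
// against [T_j, T_jp] of Q2 under the linear warp between them:
//   int_{T_i}^{T_ip} || q1(t) - sqrt(s) q2(gamma(t)) ||^2 dt,
// s = slope of gamma; trapezoid quadrature on the union of the grid points
// in [T_i, T_ip] and the preimages of those in [T_j, T_jp].
static double edge_cost(const NumericMatrix &Q1, const NumericMatrix &Q2,
                        const NumericVector &T, int i, int ip, int j, int jp,
                        std::vector<double> &bp, std::vector<double> &a,
                        std::vector<double> &b) {
  const double ti = T[i], tip = T[ip], tj = T[j], tjp = T[jp];
  const double s = (tjp - tj) / (tip - ti);
  const double sq = std::sqrt(s);

  bp.clear();
  for (int r = i; r <= ip; ++r) bp.push_back(T[r]);
  for (int q = j + 1; q < jp; ++q) bp.push_back(ti + (T[q] - tj) / s);
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end(),
                       [](double x, double y) { return std::fabs(x - y) < 1e-15; }),
           bp.end());

  const int dim = Q1.nrow();
  double cost = 0.0, f_prev = 0.0;
  for (size_t m = 0; m < bp.size(); ++m) {
    const double t = bp[m];
    interp_col(Q1, T, t, a);
    interp_col(Q2, T, tj + s * (t - ti), b);
    double f = 0.0;
    for (int d = 0; d < dim; ++d) {
      const double diff = a[d] - sq * b[d];
      f += diff * diff;
    }
    if (m > 0) cost += 0.5 * (f + f_prev) * (bp[m] - bp[m - 1]);
    f_prev = f;
  }
  return cost;
}

// [[Rcpp::export]]
double esa_edge_cost_cpp(NumericMatrix Q1, NumericMatrix Q2, NumericVector T,
                         int i, int ip, int j, int jp) {
  if (!(i < ip && j < jp))
    stop("segment indices must be strictly increasing");
  if (i < 1 || jp > T.size())
    stop("segment indices outside the grid");
  std::vector<double> bp, a(Q1.nrow()), b(Q1.nrow());
  bp.reserve(64);
  return edge_cost(Q1, Q2, T, i - 1, ip - 1, j - 1, jp - 1, bp, a, b);
}

// [[Rcpp::export]]
List esa_dp_match_cpp(NumericMatrix Q1, NumericMatrix Q2, NumericVector T,
                      int w) {
  const int n = T.size();
  if (n < 2) stop("grid must have at least 2 points");
  if (w < 1) stop("jump window must be >= 1");
  const double INF = R_PosInf;
  NumericMatrix D(n, n);
  IntegerMatrix Pa(n, n), Pb(n, n);
  std::fill(D.begin(), D.end(), INF);
  D(0, 0) = 0.0;

  std::vector<double> bp, va(Q1.nrow()), vb(Q1.nrow());
  bp.reserve(64);
  for (int i = 1; i < n; ++i) {
    const int amax = std::min(w, i);
    for (int j = 1; j < n; ++j) {
      const int bmax = std::min(w, j);
      double best = INF;
      int ba = 0, bb = 0;
      for (int a = 1; a <= amax; ++a) {
        for (int b = 1; b <= bmax; ++b) {
          const double base = D(i - a, j - b);
          if (!R_finite(base)) continue;
          const double c =
              base + edge_cost(Q1, Q2, T, i - a, i, j - b, j, bp, va, vb);
          if (c < best) {
            best = c;
            ba = a;
            bb = b;
          }
        }
      }
      D(i, j) = best;
      Pa(i, j) = ba;
      Pb(i, j) = bb;
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }

  std::vector<int> pi, pj;
  int ci = n - 1, cj = n - 1;
  while (!(ci == 0 && cj == 0)) {
    pi.push_back(ci + 1);
    pj.push_back(cj + 1);
    const int a = Pa(ci, cj), b = Pb(ci, cj);
    if (a == 0 && b == 0) stop("matching path backtrack failed");
    ci -= a;
    cj -= b;
  }
  pi.push_back(1);
  pj.push_back(1);
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return List::create(Named("cost") = D(n - 1, n - 1),
                      Named("path_i") = wrap(pi), Named("path_j") = wrap(pj));
}
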