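#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// mirror index with edge duplication: (c b a | a b c | c b a)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : period - 1 - i;
}

// Median filter over a 2D or 3D single-channel array (column-major),
// square/cubic window, reflect padding.
// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericVector median_filter_cpp(NumericVector img, IntegerVector dims, int window) {
  int nd = dims.size();
  if (nd != 2 && nd != 3) stop("median filter expects 2 or 3 spatial dimensions");
  if (window < 1 || window % 2 == 0) stop("window must be odd and positive");
  int r = window / 2;
  int d0 = dims[0], d1 = dims[1], d2 = (nd == 3) ? dims[2] : 1;
  NumericVector out(no_init(img.size()));
  int wlen = (nd == 3) ? window * window * window : window * window;
  std::vector<double> buf(wlen);
  for (int k = 0; k < d2; ++k) {
    for (int j = 0; j < d1; ++j) {
      for (int i = 0; i < d0; ++i) {
        int m = 0;
        int klo = (nd == 3) ? -r : 0, khi = (nd == 3) ? r : 0;
        for (int dk = klo; dk <= khi; ++dk) {
          int kk = reflect_idx(k + dk, d2);
          for (int dj = -r; dj <= r; ++dj) {
            int jj = reflect_idx(j + dj, d1);
            for (int di = -r; di <= r; ++di) {
              int ii = reflect_idx(i + di, d0);
              buf[m++] = img[(R_xlen_t)kk * d0 * d1 + (R_xlen_t)jj * d0 + ii];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + wlen / 2, buf.begin() + wlen);
        out[(R_xlen_t)k * d0 * d1 + (R_xlen_t)j * d0 + i] = buf[wlen / 2];
      }
    }
  }
  return out;
}

// k-means++ seeding: first centre uniform over points, each next centre drawn
// with probability proportional to the squared distance to its nearest
// already-chosen centre.  Uses R's RNG so set.seed() governs the draw.
// Returns 1-based row indices of the chosen points.
// [[Rcpp::export(name = ".kmeanspp_cpp")]]
IntegerVector kmeanspp_cpp(NumericMatrix pts, int k) {
  int n = pts.nrow(), C = pts.ncol();
  if (k < 1) stop("k must be >= 1");
  if (n < k) stop("need at least k points for k-means++ initialization");
  const double *X = pts.begin();  // n x C, column-major
  IntegerVector chosen(k);
  std::vector<double> d2(n, R_PosInf), s(n);
  int first = (int)std::floor(unif_rand() * n);
  if (first == n) first = n - 1;
  chosen[0] = first + 1;
  for (int c = 1; c < k; ++c) {
    int last = chosen[c - 1] - 1;
    std::fill(s.begin(), s.end(), 0.0);
    for (int j = 0; j < C; ++j) {
      const double *col = X + (size_t)j * n;
      double lj = col[last];
      for (int i = 0; i < n; ++i) {
        double diff = col[i] - lj;
        s[i] += diff * diff;
      }
    }
    double total = 0.0;
    for (int i = 0; i < n; ++i) {
      if (s[i] < d2[i]) d2[i] = s[i];
      total += d2[i];
    }
    int pick;
    if (total > 0.0) {
      double u = unif_rand() * total, cum = 0.0;
      pick = n - 1;
      for (int i = 0; i < n; ++i) {
        cum += d2[i];
        if (u <= cum) { pick = i; break; }
      }
    } else {
      // all points coincide with a chosen centre; fall back to uniform
      pick = (int)std::floor(unif_rand() * n);
      if (pick == n) pick = n - 1;
    }
    chosen[c] = pick + 1;
  }
  return chosen;
}

// Nearest-centroid assignment (squared Euclidean; ties to the lowest cluster
// index).  Column-sequential passes keep this cache-friendly for large n.
// Returns the within-cluster sum of squares.
static double assign_step(const double *X, int n, int C,
                          const NumericMatrix &ctr, std::vector<int> &lab,
                          std::vector<double> &score, std::vector<double> &best) {
  int k = ctr.nrow();
  std::fill(best.begin(), best.end(), R_PosInf);
  for (int c = 0; c < k; ++c) {
    double cn = 0.0;
    for (int j = 0; j < C; ++j) cn += ctr(c, j) * ctr(c, j);
    std::fill(score.begin(), score.end(), cn);  // |s_c|^2 - 2 x.s_c (+|x|^2 later)
    for (int j = 0; j < C; ++j) {
      double w = -2.0 * ctr(c, j);
      const double *col = X + (size_t)j * n;
      for (int i = 0; i < n; ++i) score[i] += w * col[i];
    }
    for (int i = 0; i < n; ++i)
      if (score[i] < best[i]) { best[i] = score[i]; lab[i] = c; }
  }
  double loss = 0.0;
  for (int i = 0; i < n; ++i) loss += best[i];
  for (int j = 0; j < C; ++j) {
    const double *col = X + (size_t)j * n;
    for (int i = 0; i < n; ++i) loss += col[i] * col[i];
  }
  return std::max(loss, 0.0);  // guard rounding on perfectly tight clusters
}

// Assign points to the nearest of fixed centroids (no update); 1-based labels.
// [[Rcpp::export(name = ".assign_cpp")]]
IntegerVector assign_cpp(NumericMatrix pts, NumericMatrix ctr) {
  int n = pts.nrow(), C = pts.ncol();
  if (ctr.ncol() != C) stop("centroid dimensionality does not match points");
  std::vector<int> lab(n);
  std::vector<double> score(n), best(n);
  assign_step(pts.begin(), n, C, ctr, lab, score, best);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = lab[i] + 1;
  return out;
}

// Lloyd iterations from given initial centres.  Stops when the assignment is
// unchanged after an iteration or max_iter is reached.  Empty clusters are
// re-seeded to the point farthest from the empty cluster's current centre.
// [[Rcpp::export(name = ".lloyd_cpp")]]
List lloyd_cpp(NumericMatrix pts, NumericMatrix init, int max_iter) {
  int n = pts.nrow(), C = pts.ncol(), k = init.nrow();
  if (max_iter < 1) stop("max_iter must be >= 1");
  if (init.ncol() != C) stop("centroid dimensionality does not match points");
  const double *X = pts.begin();
  NumericMatrix ctr = clone(init);
  std::vector<int> lab(n, -1), prev(n, -2);
  std::vector<double> score(n), best(n), trace;
  bool converged = false;
  int iter = 0;
  double loss = assign_step(X, n, C, ctr, lab, score, best);
  while (iter < max_iter) {
    ++iter;
    // update step: centroid = mean of assigned points
    std::vector<double> sums((size_t)k * C, 0.0);
    std::vector<int> cnt(k, 0);
    for (int i = 0; i < n; ++i) ++cnt[lab[i]];
    for (int j = 0; j < C; ++j) {
      const double *col = X + (size_t)j * n;
      for (int i = 0; i < n; ++i) sums[(size_t)lab[i] * C + j] += col[i];
    }
    for (int c = 0; c < k; ++c) {
      if (cnt[c] > 0) {
        for (int j = 0; j < C; ++j) ctr(c, j) = sums[(size_t)c * C + j] / cnt[c];
      } else {
        // re-seed: farthest point from this cluster's current centre
        double bestd = -1.0;
        int bi = 0;
        std::fill(score.begin(), score.end(), 0.0);
        for (int j = 0; j < C; ++j) {
          const double *col = X + (size_t)j * n;
          double cj = ctr(c, j);
          for (int i = 0; i < n; ++i) {
            double diff = col[i] - cj;
            score[i] += diff * diff;
          }
        }
        for (int i = 0; i < n; ++i)
          if (score[i] > bestd) { bestd = score[i]; bi = i; }
        for (int j = 0; j < C; ++j) ctr(c, j) = X[(size_t)j * n + bi];
      }
    }
    prev.swap(lab);
    loss = assign_step(X, n, C, ctr, lab, score, best);
    trace.push_back(loss);
    if (lab == prev) { converged = true; break; }
  }
  IntegerVector assignment(n);
  for (int i = 0; i < n; ++i) assignment[i] = lab[i] + 1;
  return List::create(_["assignment"] = assignment, _["centroids"] = ctr,
                      _["loss"] = loss, _["n_iter"] = iter,
                      _["converged"] = converged,
                      _["loss_trace"] = NumericVector(trace.begin(), trace.end()));
}
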