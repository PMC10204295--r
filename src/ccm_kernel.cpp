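#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// Shared neighbour selection + weighted prediction.
//
// Candidates are compared lexicographically by (squared distance, row
// index) so tie-breaking is deterministic and identical across kernels.
// Weights follow the exponential rule u_i = exp(-d_i / d_1); exact
// matches (d_1 = 0) share the weight mass equally.
static inline double predict_point(const std::vector<double>& bd,
                                   const std::vector<int>& bi,
                                   const NumericVector& target,
                                   int num_nbrs) {
  const double d1 = std::sqrt(bd[0]);
  double yhat = 0.0;
  if (d1 <= 0.0) {
    int nzero = 0;
    for (int i = 0; i < num_nbrs && bd[i] <= 0.0; ++i) ++nzero;
    for (int i = 0; i < nzero; ++i) yhat += target[bi[i]];
    return yhat / nzero;
  }
  double wsum = 0.0;
  for (int i = 0; i < num_nbrs; ++i) {
    const double w = std::exp(-std::sqrt(bd[i]) / d1);
    wsum += w;
    yhat += w * target[bi[i]];
  }
  return yhat / wsum;
}

static inline void insert_candidate(std::vector<double>& bd,
                                    std::vector<int>& bi, int num_nbrs,
                                    double d2, int idx) {
  int worst = num_nbrs - 1;
  if (d2 > bd[worst] || (d2 == bd[worst] && idx >= bi[worst])) return;
  int pos = worst;
  while (pos > 0 && (d2 < bd[pos - 1] ||
                     (d2 == bd[pos - 1] && idx < bi[pos - 1]))) {
    bd[pos] = bd[pos - 1];
    bi[pos] = bi[pos - 1];
    --pos;
  }
  bd[pos] = d2;
  bi[pos] = idx;
}

// Cross-map prediction for one library / predictee split.
//
// manifold: nvec x E delay-coordinate vectors; row i has origin time
//   t_index[i].  target: target-series value at each vector's origin
//   time.  lib, pred: 1-based row indices.  num_nbrs: E + 1.
// exclusion: Theiler window; library rows with |t_lib - t_pred| <=
//   exclusion are never neighbours (0 still excludes the point itself).
// Returns one estimate per predictee, NA when fewer than num_nbrs
// admissible neighbours exist.
// [[Rcpp::export]]
NumericVector ccm_predict(NumericMatrix manifold, NumericVector target,
                          IntegerVector t_index, IntegerVector lib,
                          IntegerVector pred, int num_nbrs, int exclusion) {
  const int E = manifold.ncol();
  const int nlib = lib.size();
  const int npred = pred.size();
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(npred, NA_REAL);
  std::vector<double> bd(num_nbrs);
  std::vector<int> bi(num_nbrs);

  for (int p = 0; p < npred; ++p) {
    const int pi = pred[p] - 1;
    const int tp = t_index[pi];
    std::fill(bd.begin(), bd.end(), INF);
    std::fill(bi.begin(), bi.end(), -1);
    int m = 0;
    for (int j = 0; j < nlib; ++j) {
      const int li = lib[j] - 1;
      if (std::abs(t_index[li] - tp) <= exclusion) continue;
      double d2 = 0.0;
      for (int k = 0; k < E; ++k) {
        const double diff = manifold(pi, k) - manifold(li, k);
        d2 += diff * diff;
      }
      insert_candidate(bd, bi, num_nbrs, d2, li);
      ++m;
    }
    if (m < num_nbrs) continue;
    out[p] = predict_point(bd, bi, target, num_nbrs);
  }
  return out;
}

// Batch cross-map over a grid of library lengths with replicate
// contiguous library segments.  All vectors are predictees.  Squared
// distances are precomputed once.  starts is n_reps x n_L (1-based
// segment starts); column j pairs with L_grid[j].  Returns an
// npred x (n_L * n_reps) matrix of predictions, column order
// (L1 rep1, L1 rep2, ..., L2 rep1, ...).
// [[Rcpp::export]]
NumericMatrix ccm_scan_predict(NumericMatrix manifold, NumericVector target,
                               IntegerVector t_index, IntegerVector L_grid,
                               IntegerMatrix starts, int num_nbrs,
                               int exclusion) {
  const int nvec = manifold.nrow();
  const int E = manifold.ncol();
  const int n_L = L_grid.size();
  const int n_reps = starts.nrow();
  const double INF = std::numeric_limits<double>::infinity();

  // d2[i * nvec + j], i = predictee, j = library row
  std::vector<double> d2(static_cast<size_t>(nvec) * nvec);
  for (int i = 0; i < nvec; ++i) {
    for (int j = 0; j < nvec; ++j) {
      double s = 0.0;
      for (int k = 0; k < E; ++k) {
        const double diff = manifold(i, k) - manifold(j, k);
        s += diff * diff;
      }
      d2[static_cast<size_t>(i) * nvec + j] = s;
    }
  }

  NumericMatrix out(nvec, n_L * n_reps);
  std::vector<double> bd(num_nbrs);
  std::vector<int> bi(num_nbrs);

  for (int jL = 0; jL < n_L; ++jL) {
    const int L = L_grid[jL];
    for (int r = 0; r < n_reps; ++r) {
      const int lo = starts(r, jL) - 1;
      const int hi = lo + L;  // exclusive
      const int col = jL * n_reps + r;
      for (int p = 0; p < nvec; ++p) {
        const int tp = t_index[p];
        const double* row = &d2[static_cast<size_t>(p) * nvec];
        std::fill(bd.begin(), bd.end(), INF);
        std::fill(bi.begin(), bi.end(), -1);
        int m = 0;
        for (int j = lo; j < hi; ++j) {
          if (std::abs(t_index[j] - tp) <= exclusion) continue;
          insert_candidate(bd, bi, num_nbrs, row[j], j);
          ++m;
        }
        out(p, col) = (m < num_nbrs)
          ? NA_REAL : predict_point(bd, bi, target, num_nbrs);
      }
    }
  }
  return out;
}
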