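#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Pairwise Euclidean distances between rows of an embedding matrix.
// Computed once per (E, k) configuration and reused across library subsets.
// [[Rcpp::export]]
NumericMatrix ccm_dist_matrix(NumericMatrix emb) {
  int n = emb.nrow(), d = emb.ncol();
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = emb(i, c) - emb(j, c);
        s += diff * diff;
      }
      double dist = std::sqrt(s);
      out(i, j) = dist;
      out(j, i) = dist;
    }
  }
  return out;
}

// Simplex cross-map prediction.
//   dist:   precomputed distance matrix between embedded vectors
//   lib:    0-based row indices forming the library (may contain duplicates
//           when bootstrap-resampled)
//   pred:   0-based row indices to predict at
//   target: target value aligned with each embedding row
//   nn:     number of neighbours (E + 1 for simplex projection)
// Leave-one-out: library entries equal to the prediction row are skipped.
// Ties in distance are broken by earliest row (time) index; duplicated
// library entries (bootstrap resamples) each occupy a neighbour slot. Zero
// distance to the nearest neighbour switches to uniform weights over the
// zero-distance set.
static void simplex_predict(const double* dist, int n, const int* lib, int nl,
                            const int* pred, int np, const double* target,
                            const int* times, int excl, int excl_season,
                            int nn, double* out,
                            std::vector<std::pair<double, int> >& cand) {
  // top-k selection by (distance, time index): cheap insertion into a small
  // sorted buffer beats sorting the whole candidate set for nn << |lib|
  cand.resize(nn);
  for (int p = 0; p < np; ++p) {
    int pi = pred[p];
    // the matrix is symmetric: read column pi (contiguous) instead of row pi
    const double* dcol = dist + (size_t)pi * n;
    int tpi = times[pi];
    int k = 0;
    for (int j = 0; j < nl; ++j) {
      int li = lib[j];
      if (li == pi) continue;  // leave-one-out
      int dt = times[li] - tpi;
      if (dt < 0) dt = -dt;
      if (excl > 0 && dt <= excl) continue;
      // same-calendar-month exclusion: guards against skill carried purely
      // by shared per-month offsets left over from deseasonalization
      if (excl_season && dt % 12 == 0) continue;
      std::pair<double, int> c(dcol[li], li);
      if (k == nn && !(c < cand[k - 1])) continue;
      int pos = (k < nn) ? k++ : nn - 1;
      while (pos > 0 && c < cand[pos - 1]) {
        cand[pos] = cand[pos - 1];
        --pos;
      }
      cand[pos] = c;
    }
    if (k == 0) { out[p] = NA_REAL; continue; }
    double dmin = cand[0].first;
    double num = 0.0, wsum = 0.0;
    if (dmin <= 0.0) {
      // uniform weights over coincident points
      for (int j = 0; j < k; ++j) {
        if (cand[j].first <= 0.0) {
          num += target[cand[j].second];
          wsum += 1.0;
        }
      }
    } else {
      for (int j = 0; j < k; ++j) {
        double w = std::exp(-cand[j].first / dmin);
        num += w * target[cand[j].second];
        wsum += w;
      }
    }
    out[p] = num / wsum;
  }
}

// [[Rcpp::export]]
NumericVector ccm_predict(NumericMatrix dist, IntegerVector lib,
                          IntegerVector pred, NumericVector target,
                          IntegerVector times, int excl, int excl_season,
                          int nn) {
  int np = pred.size();
  NumericVector out(np, NA_REAL);
  std::vector<std::pair<double, int> > cand;
  simplex_predict(REAL(dist), dist.nrow(), INTEGER(lib), lib.size(),
                  INTEGER(pred), np, REAL(target), INTEGER(times), excl,
                  excl_season, nn, REAL(out), cand);
  return out;
}

static double pearson(const double* x, const double* y, int n) {
  double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  int m = 0;
  for (int i = 0; i < n; ++i) {
    if (ISNAN(x[i]) || ISNAN(y[i])) continue;
    sx += x[i]; sy += y[i];
    sxx += x[i] * x[i]; syy += y[i] * y[i]; sxy += x[i] * y[i];
    ++m;
  }
  if (m < 3) return NA_REAL;
  double vx = sxx - sx * sx / m, vy = syy - sy * sy / m;
  if (vx <= 0.0 || vy <= 0.0) return NA_REAL;
  return (sxy - sx * sy / m) / std::sqrt(vx * vy);
}

// Cross-map skill for a batch of library subsets (a list of 1-based index
// vectors). Returns one Pearson rho per subset. When `out_of_lib` is true
// the skill is cross-validated: predictions are made only at points outside
// the library (falling back to leave-one-out over all points when the
// library covers everything, i.e. the full-library case); otherwise
// predictions cover every embedded point with leave-one-out.
// [[Rcpp::export]]
NumericVector ccm_rho_batch(NumericMatrix dist, List libs,
                            NumericVector target, IntegerVector times,
                            int excl, int excl_season, int nn,
                            bool out_of_lib) {
  int n = dist.nrow();
  int nb = libs.size();
  NumericVector out(nb);
  std::vector<int> pred;
  pred.reserve(n);
  std::vector<double> yhat(n);
  std::vector<double> yobs(n);
  std::vector<std::pair<double, int> > cand;
  cand.reserve(n);
  std::vector<int> lib0;
  std::vector<char> in_lib(n);
  for (int b = 0; b < nb; ++b) {
    IntegerVector lib = libs[b];
    lib0.assign(lib.begin(), lib.end());
    for (size_t j = 0; j < lib0.size(); ++j) lib0[j] -= 1;
    pred.clear();
    if (out_of_lib) {
      std::fill(in_lib.begin(), in_lib.end(), 0);
      for (size_t j = 0; j < lib0.size(); ++j) in_lib[lib0[j]] = 1;
      for (int i = 0; i < n; ++i) if (!in_lib[i]) pred.push_back(i);
    }
    if (pred.empty()) {
      for (int i = 0; i < n; ++i) pred.push_back(i);
    }
    int np = (int)pred.size();
    simplex_predict(REAL(dist), n, lib0.data(), (int)lib0.size(),
                    pred.data(), np, REAL(target), INTEGER(times), excl,
                    excl_season, nn, yhat.data(), cand);
    for (int i = 0; i < np; ++i) yobs[i] = target[pred[i]];
    out[b] = pearson(yhat.data(), yobs.data(), np);
  }
  return out;
}
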