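#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Greedy coordinate boosting with per-predictor selective stopping.
//
// The design is implicit: column (f, k) of the design matrix is predictor f
// (already convolved with the coefficient basis) delayed by lags[k] samples.
// Candidate increments are +/- step on a single (predictor, lag) coordinate;
// each iteration applies the candidate minimising the training l1 error,
// subject to the validation check: a candidate whose application would
// increase the validation l1 error is rejected, and a predictor is frozen
// once every one of its candidates is rejected.  The fit terminates when all
// predictors are frozen or max_iter is reached.
//
// xs:        T x F matrix, basis-smoothed predictors on the global time axis
// y:         length-T response (global time axis)
// lags:      K integer sample delays (may be negative)
// train_idx: 0-based global sample indices of the training rows
// val_idx:   0-based global sample indices of the validation rows
// step:      increment magnitude
// max_iter:  iteration cap
//
// Returns the coefficient matrix h (K x F), iteration count, frozen flags.

struct SparseCol {
  std::vector<int> pos;     // global sample positions with nonzero value
  std::vector<double> val;
};

static double cand_err_delta(const SparseCol &sc, int lag, double d,
                             const std::vector<int> &rank,
                             const std::vector<double> &r, int T) {
  // change in sum(|r - d * x_shifted|) relative to sum(|r|), restricted to
  // the rows selected by `rank`
  double e = 0.0;
  const size_t n = sc.pos.size();
  for (size_t i = 0; i < n; ++i) {
    const int t = sc.pos[i] + lag;
    if (t < 0 || t >= T) continue;
    const int j = rank[t];
    if (j < 0) continue;
    const double rj = r[j];
    e += std::fabs(rj - d * sc.val[i]) - std::fabs(rj);
  }
  return e;
}

static void apply_cand(const SparseCol &sc, int lag, double d,
                       const std::vector<int> &rank,
                       std::vector<double> &r, int T) {
  const size_t n = sc.pos.size();
  for (size_t i = 0; i < n; ++i) {
    const int t = sc.pos[i] + lag;
    if (t < 0 || t >= T) continue;
    const int j = rank[t];
    if (j < 0) continue;
    r[j] -= d * sc.val[i];
  }
}

// [[Rcpp::export]]
List boost_core(NumericMatrix xs, NumericVector y, IntegerVector lags,
                IntegerVector train_idx, IntegerVector val_idx,
                double step, int max_iter) {
  const int T = xs.nrow();
  const int F = xs.ncol();
  const int K = lags.size();
  const int nt = train_idx.size();
  const int nv = val_idx.size();

  // sparse view of each predictor column
  std::vector<SparseCol> cols(F);
  for (int f = 0; f < F; ++f) {
    for (int t = 0; t < T; ++t) {
      const double v = xs(t, f);
      if (v != 0.0) { cols[f].pos.push_back(t); cols[f].val.push_back(v); }
    }
  }

  // global index -> residual slot
  std::vector<int> rank_tr(T, -1), rank_va(T, -1);
  std::vector<double> r_tr(nt), r_va(nv);
  double err_tr = 0.0, err_va = 0.0;
  for (int i = 0; i < nt; ++i) {
    rank_tr[train_idx[i]] = i;
    r_tr[i] = y[train_idx[i]];
    err_tr += std::fabs(r_tr[i]);
  }
  for (int i = 0; i < nv; ++i) {
    rank_va[val_idx[i]] = i;
    r_va[i] = y[val_idx[i]];
    err_va += std::fabs(r_va[i]);
  }

  NumericMatrix h(K, F);
  std::vector<bool> frozen(F, false);
  int iter = 0;

  while (iter < max_iter) {
    ++iter;
    // training-best candidate among unfrozen predictors
    int bf = -1, bk = -1;
    double bd = 0.0, bdelta = R_PosInf;
    for (int f = 0; f < F; ++f) {
      if (frozen[f]) continue;
      for (int k = 0; k < K; ++k) {
        for (int s = -1; s <= 1; s += 2) {
          const double d = s * step;
          const double de = cand_err_delta(cols[f], lags[k], d, rank_tr,
                                           r_tr, T);
          if (de < bdelta) { bdelta = de; bf = f; bk = k; bd = d; }
        }
      }
    }
    if (bf < 0) break;  // everything frozen

    double dv = cand_err_delta(cols[bf], lags[bk], bd, rank_va, r_va, T);
    if (dv > 0.0) {
      // best training candidate fails validation: freeze the predictor
      // unless some other candidate of the same predictor passes
      int ak = -1; double ad = 0.0, adelta = R_PosInf;
      for (int k = 0; k < K; ++k) {
        for (int s = -1; s <= 1; s += 2) {
          const double d = s * step;
          const double dvc = cand_err_delta(cols[bf], lags[k], d, rank_va,
                                            r_va, T);
          if (dvc <= 0.0) {
            const double dtc = cand_err_delta(cols[bf], lags[k], d, rank_tr,
                                              r_tr, T);
            if (dtc < adelta) { adelta = dtc; ak = k; ad = d; }
          }
        }
      }
      if (ak < 0) { frozen[bf] = true; continue; }
      bk = ak; bd = ad; bdelta = adelta;
      dv = cand_err_delta(cols[bf], lags[bk], bd, rank_va, r_va, T);
    }

    h(bk, bf) += bd;
    apply_cand(cols[bf], lags[bk], bd, rank_tr, r_tr, T);
    apply_cand(cols[bf], lags[bk], bd, rank_va, r_va, T);
    err_tr += bdelta;
    err_va += dv;

    bool all_frozen = true;
    for (int f = 0; f < F; ++f) if (!frozen[f]) { all_frozen = false; break; }
    if (all_frozen) break;
  }

  LogicalVector fz(F);
  for (int f = 0; f < F; ++f) fz[f] = frozen[f];
  return List::create(_["h"] = h, _["iterations"] = iter,
                      _["frozen"] = fz, _["train_l1"] = err_tr,
                      _["val_l1"] = err_va);
}

// Predicted response from basis coefficients on the implicit lagged design:
// yhat(t) = sum_{f,k} h(k,f) * xs(t - lags[k], f)
// [[Rcpp::export]]
NumericVector design_predict(NumericMatrix xs, NumericMatrix h,
                             IntegerVector lags) {
  const int T = xs.nrow();
  const int F = xs.ncol();
  const int K = lags.size();
  NumericVector out(T);
  for (int f = 0; f < F; ++f) {
    for (int k = 0; k < K; ++k) {
      const double c = h(k, f);
      if (c == 0.0) continue;
      const int L = lags[k];
      const int t0 = std::max(0, L);
      const int t1 = std::min(T, T + L);
      for (int t = t0; t < t1; ++t) out[t] += c * xs(t - L, f);
    }
  }
  return out;
}
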