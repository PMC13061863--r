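#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Stepwise linear regression on a bordered Gram matrix via the sweep
// operator (Goodnight 1979). Working on cross-products instead of raw rows
// makes each candidate-subset fit independent of the number of epochs,
// which is what makes wrapper-style electrode selection tractable.

// Sweep pivot k of the symmetric m x m matrix S (column-major, full
// storage). A sweep followed by a reverse sweep of the same pivot restores
// the matrix (reverse = sweep + sign flip of the pivot row/column).
static void sweep_pivot(double* S, int m, int k, bool reverse) {
  const double d = S[(size_t)k * m + k];
  std::vector<double> col((size_t)m);
  for (int i = 0; i < m; ++i) col[i] = S[(size_t)k * m + i];
  for (int j = 0; j < m; ++j) {
    if (j == k) continue;
    const double f = col[j] / d;
    if (f == 0.0) continue;
    double* Sj = S + (size_t)j * m;
    for (int i = 0; i < m; ++i) Sj[i] -= col[i] * f;
  }
  const double sgn = reverse ? -1.0 : 1.0;
  for (int i = 0; i < m; ++i) {
    const double v = sgn * col[i] / d;
    S[(size_t)k * m + i] = v;
    S[(size_t)i * m + k] = v;
  }
  S[(size_t)k * m + k] = -1.0 / d;
}

struct SWCfg {
  int max_features;
  double p_enter;
  double p_remove;
  int max_iter;
  double tol;
};

// Stepwise regression of y (last column) on the feature columns 1..p of a
// bordered Gram matrix S = crossprod([1, X, y]) of dimension m = p + 2.
// n is the number of rows behind S. incl/order are filled with the
// included flags and the addition order (local indices 1..p).
// Returns the iteration count, or -1 when no feature entered the model.
static int stepwise_sweep(std::vector<double>& S, int m, int n,
                          const SWCfg& cfg, std::vector<bool>& incl,
                          std::vector<int>& order) {
  const int p = m - 2, ycol = m - 1;
  std::vector<double> d0((size_t)m);
  for (int i = 0; i < m; ++i) d0[i] = S[(size_t)i * m + i];
  sweep_pivot(S.data(), m, 0, false);  // intercept always in the model
  incl.assign((size_t)m, false);
  order.clear();
  int k = 0, it = 0;
  for (; it < cfg.max_iter; ++it) {
    bool changed = false;
    // entry: candidate with the smallest partial-F p-value, if < p_enter.
    // Within one scan all candidates share the same F degrees of freedom,
    // so the smallest p-value is attained by the largest RSS reduction;
    // only the arg-max needs an explicit p-value.
    if (k < cfg.max_features && n - k - 2 >= 1) {
      const double rss = S[(size_t)ycol * m + ycol];
      const double df2 = (double)(n - k - 2);
      int best = -1;
      double best_dr = -1.0;
      for (int j = 1; j <= p; ++j) {
        if (incl[j]) continue;
        const double dg = S[(size_t)j * m + j];
        if (!(dg > cfg.tol * d0[j]) || dg <= 0.0) continue;  // collinear
        const double sy = S[(size_t)j * m + ycol];
        const double dr = sy * sy / dg;
        if (dr > best_dr) { best = j; best_dr = dr; }
      }
      double best_p = 2.0;
      if (best >= 0) {
        const double denom = rss - best_dr;
        best_p = denom <= 0.0 ? 0.0
                 : R::pf(best_dr * df2 / denom, 1.0, df2, 0, 0);
      }
      if (best >= 0 && best_p < cfg.p_enter) {
        sweep_pivot(S.data(), m, best, false);
        incl[best] = true;
        order.push_back(best);
        ++k;
        changed = true;
      }
    }
    // removal: included column with the largest partial-F p-value, while
    // that p-value exceeds p_remove. Same monotonicity shortcut: the
    // largest p-value is attained by the smallest partial F.
    while (k > 0) {
      const int dfr = n - 1 - k;
      if (dfr < 1) break;
      const double rss = S[(size_t)ycol * m + ycol];
      const double s2 = rss / (double)dfr;
      int worst = -1;
      double worst_F = R_PosInf;
      bool degenerate = false;
      for (int j = 1; j <= p; ++j) {
        if (!incl[j]) continue;
        const double vii = -S[(size_t)j * m + j];
        const double b = S[(size_t)j * m + ycol];
        if (vii <= 0.0 || s2 <= 0.0) {  // degenerate variance: drop it
          worst = j; degenerate = true; break;
        }
        const double Fv = (b * b / vii) / s2;
        if (Fv < worst_F) { worst_F = Fv; worst = j; }
      }
      const double worst_p = degenerate ? 1.0
        : (worst >= 0 ? R::pf(worst_F, 1.0, (double)dfr, 0, 0) : -1.0);
      if (worst >= 0 && worst_p > cfg.p_remove) {
        sweep_pivot(S.data(), m, worst, true);
        incl[worst] = false;
        for (size_t q = 0; q < order.size(); ++q)
          if (order[q] == worst) { order.erase(order.begin() + q); break; }
        --k;
        changed = true;
      } else break;
    }
    if (!changed) break;
  }
  return k > 0 ? it : -1;
}

// Build the bordered sub-Gram for the feature columns `cols` (1-based
// positions in the full Gram G, whose layout is [const, feat 1..P, y]).
static void extract_sub(const double* G, int mg, const IntegerVector& cols,
                        std::vector<double>& S, std::vector<int>& gidx) {
  const int p = cols.size(), m = p + 2;
  gidx.resize((size_t)m);
  gidx[0] = 0;
  for (int i = 0; i < p; ++i) gidx[i + 1] = cols[i];
  gidx[m - 1] = mg - 1;
  S.resize((size_t)m * m);
  for (int j = 0; j < m; ++j) {
    const double* Gj = G + (size_t)gidx[j] * mg;
    double* Sj = S.data() + (size_t)j * m;
    for (int i = 0; i < m; ++i) Sj[i] = Gj[gidx[i]];
  }
}

// [[Rcpp::export]]
List cpp_stepwise_fit(NumericMatrix G, IntegerVector cols, int n,
                      int max_features, double p_enter, double p_remove,
                      int max_iter, double tol) {
  const int mg = G.nrow();
  SWCfg cfg{max_features, p_enter, p_remove, max_iter, tol};
  std::vector<double> S;
  std::vector<int> gidx;
  extract_sub(G.begin(), mg, cols, S, gidx);
  const int m = cols.size() + 2, ycol = m - 1;
  std::vector<bool> incl;
  std::vector<int> order;
  const int it = stepwise_sweep(S, m, n, cfg, incl, order);
  if (it < 0)
    return List::create(_["ok"] = false);
  const int k = (int)order.size();
  IntegerVector included(k);
  NumericVector weights(k);
  for (int q = 0; q < k; ++q) {
    included[q] = cols[order[q] - 1];           // global feature column
    weights[q] = S[(size_t)order[q] * m + ycol];
  }
  return List::create(_["ok"] = true, _["included"] = included,
                      _["weights"] = weights,
                      _["intercept"] = S[(size_t)0 * m + ycol],
                      _["rss"] = S[(size_t)ycol * m + ycol],
                      _["iterations"] = it + 1,
                      _["converged"] = it < max_iter);
}

// Fit a stepwise model on the training Gram for every candidate column set
// and count correctly classified trials on the supplied test epochs at
// every flash count r = 1..max_occ. rows: 1-based epoch indices of the test
// half; trial/choice/occ are per-epoch (trial is a local 1..n_trials
// index); target is per-trial. Returns a sets x max_occ matrix of correct
// trial counts; the whole row is -1 when the fit failed (no feature
// entered).
// [[Rcpp::export]]
IntegerMatrix cpp_eval_sets(NumericMatrix G, int n_train, List sets,
                            NumericMatrix X, IntegerVector rows,
                            IntegerVector trial, IntegerVector choice,
                            IntegerVector occ, IntegerVector target,
                            IntegerVector active_trials, int n_choices,
                            int max_occ, int max_features, double p_enter,
                            double p_remove, int max_iter, double tol) {
  const int mg = G.nrow();
  const int n_trials = target.size();
  SWCfg cfg{max_features, p_enter, p_remove, max_iter, tol};
  IntegerMatrix out(sets.size(), max_occ);
  std::vector<double> S, sums((size_t)n_trials * n_choices * max_occ);
  std::vector<int> gidx, order;
  std::vector<bool> incl;
  for (int s = 0; s < sets.size(); ++s) {
    IntegerVector cols = sets[s];
    extract_sub(G.begin(), mg, cols, S, gidx);
    const int m = cols.size() + 2, ycol = m - 1;
    const int it = stepwise_sweep(S, m, n_train, cfg, incl, order);
    if (it < 0) {
      for (int r = 0; r < max_occ; ++r) out(s, r) = -1;
      continue;
    }
    const int k = (int)order.size();
    std::vector<int> xcol((size_t)k);
    std::vector<double> w((size_t)k);
    for (int q = 0; q < k; ++q) {
      xcol[q] = cols[order[q] - 1] - 1;  // 0-based column of X
      w[q] = S[(size_t)order[q] * m + ycol];
    }
    const double b0 = S[(size_t)0 * m + ycol];
    std::fill(sums.begin(), sums.end(), 0.0);
    const int nr = X.nrow();
    const size_t plane = (size_t)n_trials * n_choices;
    for (int e = 0; e < rows.size(); ++e) {
      const int row = rows[e] - 1;
      if (occ[row] > max_occ) continue;
      double sc = b0;
      for (int q = 0; q < k; ++q) sc += w[q] * X[(size_t)xcol[q] * nr + row];
      sums[(size_t)(trial[row] - 1) + (size_t)(choice[row] - 1) * n_trials +
           (size_t)(occ[row] - 1) * plane] += sc;
    }
    // cumulative over occurrences: sums at plane r = summed score of the
    // first r+1 flashes of each choice
    for (int r = 1; r < max_occ; ++r)
      for (size_t i = 0; i < plane; ++i)
        sums[(size_t)r * plane + i] += sums[(size_t)(r - 1) * plane + i];
    for (int r = 0; r < max_occ; ++r) {
      int correct = 0;
      const double* pl = sums.data() + (size_t)r * plane;
      for (int a = 0; a < active_trials.size(); ++a) {
        const int t = active_trials[a] - 1;
        int pred = 0;
        double best = pl[(size_t)t];
        for (int c = 1; c < n_choices; ++c) {
          const double v = pl[(size_t)t + (size_t)c * n_trials];
          if (v > best) { best = v; pred = c; }
        }
        if (pred + 1 == target[t]) ++correct;
      }
      out(s, r) = correct;
    }
  }
  return out;
}
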