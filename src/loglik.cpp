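#include <Rcpp.h>
using namespace Rcpp;

// Batched cohort log-likelihood.
//
// theta: n_theta x k matrix of parameter vectors laid out as in
// param_names(): b (one per level), t (one per arc), p_late last.
// ctx: the list built by likelihood_context() -- state bits, per-level
// parent-subset tables, observation probabilities of the cohort's unique
// diagnosis patterns and their per-T-category counts.
//
// Returns one log-likelihood per row of theta; -Inf for parameter vectors
// outside the unit cube or assigning probability zero to an observed
// pattern.
//
// The transition kernel factorizes over levels, so each column of A (one
// source state) is the Kronecker product of V per-level 2-vectors over the
// destination bit; building columns by iterated doubling costs 2n
// multiplies per column instead of n*V.
// [[Rcpp::export]]
NumericVector cohort_loglik_core(NumericMatrix theta, List ctx) {
  const IntegerMatrix bits_m = ctx["bits"];
  const IntegerMatrix psub_m = ctx["psub"];
  const List subs = ctx["subs"];
  const NumericMatrix obs_m = ctx["obs"];
  const NumericVector cnt_early = ctx["count_early"];
  const NumericVector cnt_late = ctx["count_late"];
  const double p_early = as<double>(ctx["p_early"]);
  const int t_max = as<int>(ctx["t_max"]);

  const int n = bits_m.nrow();   // number of hidden states
  const int V = bits_m.ncol();
  const int npat = obs_m.nrow();
  const int k = theta.ncol();
  const int n_theta = theta.nrow();

  // flat copies for tight loops (column-major like the R matrices)
  std::vector<int> bits(bits_m.begin(), bits_m.end());
  std::vector<int> psub(psub_m.begin(), psub_m.end());
  std::vector<double> obs((size_t) n * npat);     // obs[s + n*p]
  for (int p = 0; p < npat; ++p)
    for (int s = 0; s < n; ++s)
      obs[s + (size_t) n * p] = obs_m(p, s);

  std::vector<std::vector<std::vector<int> > > sub_tidx(V);
  for (int v = 0; v < V; ++v) {
    List sv = subs[v];
    sub_tidx[v].resize(sv.size());
    for (int s = 0; s < sv.size(); ++s) {
      IntegerVector tid = sv[s];
      sub_tidx[v][s].assign(tid.begin(), tid.end());
    }
  }

  std::vector<double> w_e(t_max + 1), w_l(t_max + 1);
  for (int t = 0; t <= t_max; ++t)
    w_e[t] = R::dbinom(t, t_max, p_early, 0);

  NumericVector out(n_theta);
  std::vector<double> A((size_t) n * n), cur(n), nxt(n), dist_e(n), dist_l(n);
  std::vector<std::vector<double> > sp(V);

  for (int it = 0; it < n_theta; ++it) {
    bool ok = true;
    for (int c = 0; c < k; ++c) {
      double x = theta(it, c);
      if (!(x >= 0.0 && x <= 1.0)) { ok = false; break; }
    }
    if (!ok) { out[it] = R_NegInf; continue; }

    // spread probability into each level for every involved-parent subset
    for (int v = 0; v < V; ++v) {
      int ns = (int) sub_tidx[v].size();
      sp[v].assign(ns, 0.0);
      double bv = theta(it, v);
      for (int s = 0; s < ns; ++s) {
        double q = 1.0 - bv;
        for (size_t u = 0; u < sub_tidx[v][s].size(); ++u)
          q *= 1.0 - theta(it, sub_tidx[v][s][u]);
        sp[v][s] = 1.0 - q;
      }
    }

    // transition matrix, column j = source state; level 1 is the most
    // significant destination bit, so expand it first
    for (int j = 0; j < n; ++j) {
      double *col = &A[(size_t) n * j];
      col[0] = 1.0;
      int len = 1;
      for (int v = 0; v < V; ++v) {
        double f0, f1;
        if (bits[j + n * v]) {          // involved stays involved
          f0 = 0.0; f1 = 1.0;
        } else {
          double s = sp[v][psub[j + n * v]];
          f0 = 1.0 - s; f1 = s;
        }
        for (int idx = len - 1; idx >= 0; --idx) {
          double o = col[idx];
          col[2 * idx + 1] = o * f1;
          col[2 * idx]     = o * f0;
        }
        len *= 2;
      }
    }

    // evolve from all-healthy, marginalizing both diagnose-time priors
    double p_late = theta(it, k - 1);
    for (int t = 0; t <= t_max; ++t)
      w_l[t] = R::dbinom(t, t_max, p_late, 0);
    std::fill(cur.begin(), cur.end(), 0.0);
    cur[0] = 1.0;
    for (int s = 0; s < n; ++s) {
      dist_e[s] = w_e[0] * cur[s];
      dist_l[s] = w_l[0] * cur[s];
    }
    for (int t = 1; t <= t_max; ++t) {
      std::fill(nxt.begin(), nxt.end(), 0.0);
      for (int j = 0; j < n; ++j) {
        double pj = cur[j];
        if (pj == 0.0) continue;
        const double *col = &A[(size_t) n * j];
        for (int i = 0; i < n; ++i) nxt[i] += col[i] * pj;
      }
      std::swap(cur, nxt);
      double we = w_e[t], wl = w_l[t];
      for (int s = 0; s < n; ++s) {
        dist_e[s] += we * cur[s];
        dist_l[s] += wl * cur[s];
      }
    }

    double ll = 0.0;
    for (int p = 0; p < npat && ok; ++p) {
      const double *op = &obs[(size_t) n * p];
      if (cnt_early[p] > 0) {
        double q = 0.0;
        for (int s = 0; s < n; ++s) q += op[s] * dist_e[s];
        if (q <= 0.0) { ok = false; break; }
        ll += cnt_early[p] * std::log(q);
      }
      if (cnt_late[p] > 0) {
        double q = 0.0;
        for (int s = 0; s < n; ++s) q += op[s] * dist_l[s];
        if (q <= 0.0) { ok = false; break; }
        ll += cnt_late[p] * std::log(q);
      }
    }
    out[it] = ok ? ll : R_NegInf;
  }
  return out;
}
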