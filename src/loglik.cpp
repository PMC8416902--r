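// Hot path of the linear z-score event model: piecewise-linear trajectory
// construction and the stage-marginalized Gaussian log-likelihood. These are
// evaluated tens of thousands of times during greedy sequence optimization,
// EM, and MCMC, so they live in C++.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Build the scaled trajectory matrix Ts ((S+1) x B, divided by sigma) for a
// sequence. Events are ordered by biomarker then threshold, so each
// biomarker's events occupy a contiguous id range.
static void build_traj(const IntegerVector& seqv, const IntegerVector& bm_id,
                       const NumericVector& z_ev, const NumericVector& max_z,
                       const NumericVector& inv_sigma, int B,
                       std::vector<double>& Ts) {
  const int S = seqv.size();
  std::vector<int> pos_of(S + 1);
  for (int p = 0; p < S; ++p) pos_of[seqv[p]] = p + 1;  // 1-based positions

  std::vector<double> kx, ky;
  int ev = 0;
  for (int b = 0; b < B; ++b) {
    kx.clear(); ky.clear();
    kx.push_back(0.0); ky.push_back(0.0);
    // collect this biomarker's events (contiguous, z ascending)
    int first = ev;
    while (ev < S && bm_id[ev] == b + 1) ++ev;
    int m = ev - first;
    // positions are increasing for a valid sequence; sort defensively
    std::vector<std::pair<int, double> > knots(m);
    for (int j = 0; j < m; ++j)
      knots[j] = std::make_pair(pos_of[first + j + 1], z_ev[first + j]);
    std::sort(knots.begin(), knots.end());
    for (int j = 0; j < m; ++j) {
      kx.push_back((double)knots[j].first);
      ky.push_back(knots[j].second);
    }
    if (kx.back() < S) { kx.push_back((double)S); ky.push_back(max_z[b]); }
    // evaluate at integer stages 0..S
    int seg = 0, nseg = (int)kx.size() - 1;
    for (int k = 0; k <= S; ++k) {
      while (seg < nseg - 1 && k > kx[seg + 1]) ++seg;
      double x0 = kx[seg], x1 = kx[seg + 1];
      double y = ky[seg] + (ky[seg + 1] - ky[seg]) * (k - x0) / (x1 - x0);
      Ts[(size_t)k * B + b] = y * inv_sigma[b];
    }
  }
}

// Per-subject stage-marginalized log-likelihood for one sequence.
// Zs: n x B data scaled by 1/sigma; cz: per-subject constant
// (-B/2 log(2 pi) - sum log sigma - 0.5 ||z_j||^2).
// [[Rcpp::export]]
NumericVector seq_marginal_loglik_cpp(const NumericMatrix& Zs,
                                      const NumericVector& cz,
                                      const IntegerVector& seqv,
                                      const IntegerVector& bm_id,
                                      const NumericVector& z_ev,
                                      const NumericVector& max_z,
                                      const NumericVector& inv_sigma,
                                      double log_stages) {
  const int n = Zs.nrow(), B = Zs.ncol(), S = seqv.size();
  std::vector<double> Ts((size_t)(S + 1) * B);
  build_traj(seqv, bm_id, z_ev, max_z, inv_sigma, B, Ts);

  std::vector<double> tt(S + 1);
  for (int k = 0; k <= S; ++k) {
    double s = 0.0;
    for (int b = 0; b < B; ++b) {
      double v = Ts[(size_t)k * B + b];
      s += v * v;
    }
    tt[k] = 0.5 * s;
  }

  // acc[j + n*k] = dot(Zs_j, Ts_k), accumulated column-major for locality
  std::vector<double> acc((size_t)n * (S + 1), 0.0);
  const double* zp = &Zs(0, 0);
  for (int b = 0; b < B; ++b) {
    const double* zcol = zp + (size_t)n * b;
    for (int k = 0; k <= S; ++k) {
      const double t = Ts[(size_t)k * B + b];
      if (t == 0.0) continue;
      double* a = &acc[(size_t)n * k];
      for (int j = 0; j < n; ++j) a[j] += zcol[j] * t;
    }
  }
  NumericVector out(n);
  for (int j = 0; j < n; ++j) {
    double mx = R_NegInf;
    for (int k = 0; k <= S; ++k) {
      double v = acc[(size_t)n * k + j] - tt[k];
      if (v > mx) mx = v;
    }
    double s = 0.0;
    for (int k = 0; k <= S; ++k)
      s += std::exp(acc[(size_t)n * k + j] - tt[k] - mx);
    out[j] = cz[j] + mx + std::log(s) - log_stages;
  }
  return out;
}

// Weighted sum of the per-subject marginal log-likelihoods (the greedy and
// MCMC objective), avoiding the return-vector allocation.
// [[Rcpp::export]]
double seq_weighted_loglik_cpp(const NumericMatrix& Zs,
                               const NumericVector& cz,
                               const NumericVector& w,
                               const IntegerVector& seqv,
                               const IntegerVector& bm_id,
                               const NumericVector& z_ev,
                               const NumericVector& max_z,
                               const NumericVector& inv_sigma,
                               double log_stages) {
  const int n = Zs.nrow(), B = Zs.ncol(), S = seqv.size();
  std::vector<double> Ts((size_t)(S + 1) * B);
  build_traj(seqv, bm_id, z_ev, max_z, inv_sigma, B, Ts);
  std::vector<double> tt(S + 1);
  for (int k = 0; k <= S; ++k) {
    double s = 0.0;
    for (int b = 0; b < B; ++b) {
      double v = Ts[(size_t)k * B + b];
      s += v * v;
    }
    tt[k] = 0.5 * s;
  }
  std::vector<double> acc((size_t)n * (S + 1), 0.0);
  const double* zp = &Zs(0, 0);
  for (int b = 0; b < B; ++b) {
    const double* zcol = zp + (size_t)n * b;
    for (int k = 0; k <= S; ++k) {
      const double t = Ts[(size_t)k * B + b];
      if (t == 0.0) continue;
      double* a = &acc[(size_t)n * k];
      for (int j = 0; j < n; ++j) a[j] += zcol[j] * t;
    }
  }
  double total = 0.0;
  for (int j = 0; j < n; ++j) {
    if (w[j] == 0.0) continue;
    double mx = R_NegInf;
    for (int k = 0; k <= S; ++k) {
      double v = acc[(size_t)n * k + j] - tt[k];
      if (v > mx) mx = v;
    }
    double s = 0.0;
    for (int k = 0; k <= S; ++k)
      s += std::exp(acc[(size_t)n * k + j] - tt[k] - mx);
    total += w[j] * (cz[j] + mx + std::log(s) - log_stages);
  }
  return total;
}
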