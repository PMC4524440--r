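#include <Rcpp.h>
using namespace Rcpp;

// Counts are stored as doubles: integers are exact up to 2^53, which covers
// the 1e11-cell regimes simulated here. All draws below return whole numbers.

// Binomial(n, p) for n possibly far beyond 32-bit. Below 1e9 we defer to R's
// exact sampler; above it we use a moment-matched rounded normal, clamped to
// [0, n] so totals are conserved and counts stay non-negative.
static double rbinom_big(double n, double p) {
  if (n <= 0.0 || p <= 0.0) return 0.0;
  if (p >= 1.0) return n;
  if (n < 1e9) return R::rbinom(n, p);
  double m = n * p;
  double sd = std::sqrt(n * p * (1.0 - p));
  double x = std::floor(m + sd * norm_rand() + 0.5);
  if (x < 0.0) x = 0.0;
  if (x > n) x = n;
  return x;
}

// Multinomial(n; p[0..k-1]) by sequential conditional binomials. The last
// category takes the remainder, so the draw always sums to n exactly.
static void rmultinom_big(double n, const double *p, int k, double *out) {
  double rem = n;
  double prem = 1.0;
  for (int t = 0; t < k - 1; ++t) {
    double q = (prem > 0.0) ? p[t] / prem : 0.0;
    if (q > 1.0) q = 1.0;
    double x = rbinom_big(rem, q);
    out[t] = x;
    rem -= x;
    prem -= p[t];
  }
  out[k - 1] = rem;
}

// One synchronous step of the branching process on the (i, j) lattice.
// Fates per cell: death; plain division; division with a driver mutation in
// one daughter; division with a resistance mutation in one daughter.
// Driver mutations are impossible at i = N, resistance mutations at j = 1
// (the mutation is wasted; its probability mass folds into plain division).
// Returns the number of subclones whose fitness had to be clipped to [-1, 1].
static int do_step(const NumericMatrix &cur, NumericMatrix &nxt, double sigma,
                   double s, double c, double u, double v, int N) {
  int clips = 0;
  std::fill(nxt.begin(), nxt.end(), 0.0);
  for (int j = 0; j <= 1; ++j) {
    for (int i = 0; i <= N; ++i) {
      double n = cur(i, j);
      if (n <= 0.0) continue;
      double f = s * (i + 1) - sigma * (1 - j) - c * j;
      if (f > 1.0) { f = 1.0; ++clips; }
      if (f < -1.0) { f = -1.0; ++clips; }
      double b = 0.5 * (1.0 + f);
      double d = 0.5 * (1.0 - f);
      double uu = (i < N) ? u : 0.0;
      double vv = (j == 0) ? v : 0.0;
      double probs[4] = { d, b * (1.0 - uu - vv), b * uu, b * vv };
      double fates[4];
      rmultinom_big(n, probs, 4, fates);
      nxt(i, j) += 2.0 * fates[1] + fates[2] + fates[3];
      if (fates[2] > 0.0) nxt(i + 1, j) += fates[2];
      if (fates[3] > 0.0) nxt(i, 1) += fates[3];
    }
  }
  return clips;
}

static double mat_total(const NumericMatrix &m) {
  double t = 0.0;
  for (R_xlen_t k = 0; k < m.size(); ++k) t += m[k];
  return t;
}

static double mat_resistant(const NumericMatrix &m) {
  double t = 0.0;
  int nr = m.nrow();
  for (int i = 0; i < nr; ++i) t += m(i, 1);
  return t;
}

// [[Rcpp::export]]
List cpp_step(NumericMatrix counts, double sigma, double s, double c,
              double u, double v) {
  int N = counts.nrow() - 1;
  NumericMatrix nxt(counts.nrow(), 2);
  int clips = do_step(counts, nxt, sigma, s, c, u, v, N);
  return List::create(_["counts"] = nxt, _["clips"] = clips);
}

// Run the process until total >= target (status 0), extinction (status 1)
// or max_steps elapsed (status 2). Detection is checked after each completed
// step, and once before the first step so a start at or above target exits
// with 0 steps. With metronomic = true the intensity sigma is applied on a
// step only when sensitive cells outnumber resistant cells.
// When record = true the per-step total and resistant totals are returned.
// [[Rcpp::export]]
List cpp_run(NumericMatrix counts, double sigma, bool metronomic, double s,
             double c, double u, double v, double target, int max_steps,
             bool record) {
  int N = counts.nrow() - 1;
  NumericMatrix cur = clone(counts);
  NumericMatrix nxt(counts.nrow(), 2);
  std::vector<double> tot_tr, res_tr;
  if (record) {
    tot_tr.reserve(max_steps < 20000 ? max_steps : 20000);
    res_tr.reserve(max_steps < 20000 ? max_steps : 20000);
  }
  double total = mat_total(cur);
  int status = (total >= target) ? 0 : 2;
  int steps = 0;
  long clips = 0;
  if (status != 0) {
    while (steps < max_steps) {
      double sig_eff = sigma;
      if (metronomic) {
        double resi = mat_resistant(cur);
        sig_eff = ((total - resi) > resi) ? sigma : 0.0;
      }
      clips += do_step(cur, nxt, sig_eff, s, c, u, v, N);
      std::swap(cur, nxt);
      ++steps;
      total = mat_total(cur);
      if (record) {
        tot_tr.push_back(total);
        res_tr.push_back(mat_resistant(cur));
      }
      if (total <= 0.0) { status = 1; break; }
      if (total >= target) { status = 0; break; }
    }
  }
  List out = List::create(
      _["counts"] = cur, _["steps"] = steps, _["status"] = status,
      _["clips"] = (double)clips,
      _["total_traj"] = record ? wrap(tot_tr) : R_NilValue,
      _["resist_traj"] = record ? wrap(res_tr) : R_NilValue);
  return out;
}
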