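#include <Rcpp.h>
using namespace Rcpp;

// Duration-dependent (semi-Markov) Viterbi over a fixed cyclic state order.
//
// loglik: T x S frame log-likelihoods, states in cyclic order
//         (state s is always followed by (s+1) mod S).
// logpmf: D x S log duration pmf (integer durations 1..D), -Inf outside the
//         admissible range.
// logsurv: D x S log survival P(duration >= d), used for the censored first
//          and last runs (a run may begin before frame 1 or extend past T).
// Returns the 0-based maximum a-posteriori state per frame.
// [[Rcpp::export]]
IntegerVector hsmm_viterbi_cpp(NumericMatrix loglik, NumericMatrix logpmf,
                               NumericMatrix logsurv) {
  const int T = loglik.nrow(), S = loglik.ncol(), D = logpmf.nrow();
  const double NEG = -1e300;
  // cumulative emission log-likelihood per state
  std::vector<double> cum((T + 1) * S);
  for (int s = 0; s < S; s++) {
    cum[s] = 0.0;
    for (int t = 0; t < T; t++)
      cum[(t + 1) * S + s] = cum[t * S + s] + loglik(t, s);
  }
  // delta[t][s]: best log score of a segmentation of frames 1..t whose final
  // run is state s ending exactly at t. psi stores the winning duration.
  std::vector<double> delta((T + 1) * S, NEG);
  std::vector<int> psi((T + 1) * S, 0);
  for (int t = 1; t <= T; t++) {
    const bool last = (t == T);
    for (int s = 0; s < S; s++) {
      double best = NEG; int bestd = 0;
      const int dmax = std::min(D, t);
      const int sp = (s + S - 1) % S;
      for (int d = 1; d <= dmax; d++) {
        const bool first = (t - d == 0);
        double durterm = (first || last) ? logsurv(d - 1, s) : logpmf(d - 1, s);
        if (durterm <= NEG || durterm == R_NegInf) continue;
        double prev = first ? 0.0 : delta[(t - d) * S + sp];
        if (prev <= NEG) continue;
        double sc = prev + durterm + cum[t * S + s] - cum[(t - d) * S + s];
        if (sc > best) { best = sc; bestd = d; }
      }
      delta[t * S + s] = best;
      psi[t * S + s] = bestd;
    }
  }
  int s = 0; double best = delta[T * S];
  for (int k = 1; k < S; k++)
    if (delta[T * S + k] > best) { best = delta[T * S + k]; s = k; }
  if (best <= NEG) stop("HSMM decode failure: no admissible state path");
  IntegerVector path(T);
  int t = T;
  while (t > 0) {
    int d = psi[t * S + s];
    if (d <= 0) stop("HSMM decode failure during backtrack");
    for (int i = t - d; i < t; i++) path[i] = s;
    t -= d;
    s = (s + S - 1) % S;
  }
  return path;
}

// Sample entropy SampEn(m, r): -log(A/B) where B counts template pairs
// matching for m points and A those also matching for m+1 points (Chebyshev
// distance <= r, self-matches excluded). Returns +Inf when A == 0 and NA when
// no m-templates match at all.
// [[Rcpp::export]]
double sampen_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  if (n < m + 2) return NA_REAL;
  long long A = 0, B = 0;
  const int nt = n - m; // number of (m+1)-length templates = n - m
  // iterate by lag so both template reads are sequential
  for (int h = 1; h < nt; h++) {
    for (int i = 0; i + h < nt; i++) {
      double d = 0.0;
      for (int k = 0; k < m; k++) {
        double dd = std::fabs(x[i + k] - x[i + h + k]);
        if (dd > d) d = dd;
      }
      if (d <= r) {
        B++;
        if (std::fabs(x[i + m] - x[i + h + m]) <= r) A++;
      }
    }
  }
  if (B == 0) return NA_REAL;
  if (A == 0) return R_PosInf;
  return -std::log((double)A / (double)B);
}
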