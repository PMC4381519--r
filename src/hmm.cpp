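#include <Rcpp.h>
using namespace Rcpp;

// Two-state HMM recursions in log space.  Sites are grouped into independent
// chains (offsets: 0-based row offsets of chain starts, plus the total row
// count as the final element).  State 0 = protected (MPR), 1 = accessible
// (MAR); ties in the Viterbi back-pointers and at the terminal state resolve
// toward state 0.

static inline double logsumexp2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = (a > b) ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericMatrix logemit, NumericMatrix loga, NumericVector logpi,
            IntegerVector offsets) {
  int T = logemit.nrow();
  int nchain = offsets.size() - 1;
  NumericMatrix gamma(T, 2);
  NumericMatrix xi(2, 2);        // expected transition counts, summed
  NumericVector first(2);        // summed start-of-chain responsibilities
  double loglik = 0.0;

  std::vector<double> la(T), lb(T); // alpha/beta for state 0
  std::vector<double> la1(T), lb1(T);

  for (int c = 0; c < nchain; ++c) {
    int s = offsets[c], e = offsets[c + 1];
    if (e <= s) continue;
    la[s]  = logpi[0] + logemit(s, 0);
    la1[s] = logpi[1] + logemit(s, 1);
    for (int t = s + 1; t < e; ++t) {
      la[t]  = logsumexp2(la[t - 1] + loga(0, 0), la1[t - 1] + loga(1, 0)) +
               logemit(t, 0);
      la1[t] = logsumexp2(la[t - 1] + loga(0, 1), la1[t - 1] + loga(1, 1)) +
               logemit(t, 1);
    }
    double ll = logsumexp2(la[e - 1], la1[e - 1]);
    loglik += ll;
    lb[e - 1] = 0.0;
    lb1[e - 1] = 0.0;
    for (int t = e - 2; t >= s; --t) {
      lb[t]  = logsumexp2(loga(0, 0) + logemit(t + 1, 0) + lb[t + 1],
                          loga(0, 1) + logemit(t + 1, 1) + lb1[t + 1]);
      lb1[t] = logsumexp2(loga(1, 0) + logemit(t + 1, 0) + lb[t + 1],
                          loga(1, 1) + logemit(t + 1, 1) + lb1[t + 1]);
    }
    for (int t = s; t < e; ++t) {
      gamma(t, 0) = std::exp(la[t] + lb[t] - ll);
      gamma(t, 1) = std::exp(la1[t] + lb1[t] - ll);
    }
    first[0] += gamma(s, 0);
    first[1] += gamma(s, 1);
    for (int t = s; t < e - 1; ++t) {
      xi(0, 0) += std::exp(la[t]  + loga(0, 0) + logemit(t + 1, 0) + lb[t + 1]  - ll);
      xi(0, 1) += std::exp(la[t]  + loga(0, 1) + logemit(t + 1, 1) + lb1[t + 1] - ll);
      xi(1, 0) += std::exp(la1[t] + loga(1, 0) + logemit(t + 1, 0) + lb[t + 1]  - ll);
      xi(1, 1) += std::exp(la1[t] + loga(1, 1) + logemit(t + 1, 1) + lb1[t + 1] - ll);
    }
  }
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi"] = xi, _["first"] = first);
}

// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(NumericMatrix logemit, NumericMatrix loga,
                          NumericVector logpi, IntegerVector offsets) {
  int T = logemit.nrow();
  int nchain = offsets.size() - 1;
  IntegerVector path(T);
  std::vector<double> d0(T), d1(T);
  std::vector<int> bp0(T), bp1(T);

  for (int c = 0; c < nchain; ++c) {
    int s = offsets[c], e = offsets[c + 1];
    if (e <= s) continue;
    d0[s] = logpi[0] + logemit(s, 0);
    d1[s] = logpi[1] + logemit(s, 1);
    for (int t = s + 1; t < e; ++t) {
      // into state 0: prefer predecessor 0 on ties
      double f0 = d0[t - 1] + loga(0, 0), f1 = d1[t - 1] + loga(1, 0);
      if (f1 > f0) { d0[t] = f1 + logemit(t, 0); bp0[t] = 1; }
      else         { d0[t] = f0 + logemit(t, 0); bp0[t] = 0; }
      f0 = d0[t - 1] + loga(0, 1); f1 = d1[t - 1] + loga(1, 1);
      if (f1 > f0) { d1[t] = f1 + logemit(t, 1); bp1[t] = 1; }
      else         { d1[t] = f0 + logemit(t, 1); bp1[t] = 0; }
    }
    int st = (d1[e - 1] > d0[e - 1]) ? 1 : 0;
    path[e - 1] = st;
    for (int t = e - 1; t > s; --t) {
      st = (st == 0) ? bp0[t] : bp1[t];
      path[t - 1] = st;
    }
  }
  return path;
}
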