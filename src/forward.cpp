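#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse3(double a, double b, double c) {
  double m = a;
  if (b > m) m = b;
  if (c > m) m = c;
  if (m == NEG_INF) return NEG_INF;
  return m + std::log(std::exp(a - m) + std::exp(b - m) + std::exp(c - m));
}

// Forward algorithm over a global-mode profile HMM (match/insert/delete per
// node, begin = node 0, end after node K). All inputs are natural-log
// probabilities. seq holds 1-based residue indices into the emission
// columns, or 0 for an unknown residue, which emits with probability 1 in
// both the model and the background so it cancels in the log-odds.
//
// tM/tI/tD: (K+1) x 3 rows j = 0..K, columns = transitions to
// {M_{j+1} (or end at j = K), I_j, D_{j+1}}.
// eM: K x 20 log match emissions; eI: (K+1) x 20 log insert emissions.
// [[Rcpp::export]]
double forward_logprob_cpp(NumericMatrix tM, NumericMatrix tI,
                           NumericMatrix tD, NumericMatrix eM,
                           NumericMatrix eI, IntegerVector seq) {
  const int K = eM.nrow();
  const int L = seq.size();
  std::vector<double> Mprev(K + 1, NEG_INF), Iprev(K + 1, NEG_INF),
      Dprev(K + 1, NEG_INF);
  std::vector<double> Mcur(K + 1), Icur(K + 1), Dcur(K + 1);

  // i = 0: begin state M_0, plus delete chain reachable without emitting
  Mprev[0] = 0.0;
  for (int j = 1; j <= K; ++j) {
    Dprev[j] = lse3(Mprev[j - 1] + tM(j - 1, 2), Iprev[j - 1] + tI(j - 1, 2),
                    Dprev[j - 1] + tD(j - 1, 2));
  }

  for (int i = 1; i <= L; ++i) {
    const int x = seq[i - 1] - 1;  // -1 => unknown
    for (int j = 0; j <= K; ++j) {
      if (j == 0) {
        Mcur[0] = NEG_INF;
      } else {
        double em = (x >= 0) ? eM(j - 1, x) : 0.0;
        Mcur[j] = em + lse3(Mprev[j - 1] + tM(j - 1, 0),
                            Iprev[j - 1] + tI(j - 1, 0),
                            Dprev[j - 1] + tD(j - 1, 0));
      }
      double ei = (x >= 0) ? eI(j, x) : 0.0;
      Icur[j] = ei + lse3(Mprev[j] + tM(j, 1), Iprev[j] + tI(j, 1),
                          Dprev[j] + tD(j, 1));
      if (j == 0) {
        Dcur[0] = NEG_INF;
      } else {
        Dcur[j] = lse3(Mcur[j - 1] + tM(j - 1, 2), Icur[j - 1] + tI(j - 1, 2),
                       Dcur[j - 1] + tD(j - 1, 2));
      }
    }
    Mprev = Mcur;
    Iprev = Icur;
    Dprev = Dcur;
  }

  return lse3(Mprev[K] + tM(K, 0), Iprev[K] + tI(K, 0),
              Dprev[K] + tD(K, 0));
}
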