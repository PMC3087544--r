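#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// numerically stable log(exp(a) + exp(b))
static inline double logadd(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log1p(std::exp((a > b ? b : a) - m));
}

static inline double comb3(double a, double b, double c, bool viterbi) {
  if (viterbi) return std::max(a, std::max(b, c));
  return logadd(logadd(a, b), c);
}

// Local (free start/end) profile score in natural-log odds space.
// em: k x L match-emission log-odds; lM/lI: (k+1) x 3 log transitions
// (rows = source position 0..k, cols = to M / to I / to D); lD: k x 3
// (rows = source D_1..D_k). Entry at any match state with weight 1/k,
// exit free after any match state; insert states emit background (odds 0).
// [[Rcpp::export(name = ".profile_forward_local")]]
double profile_forward_local(NumericMatrix em, NumericMatrix lM,
                             NumericMatrix lI, NumericMatrix lD,
                             bool viterbi) {
  int k = em.nrow(), L = em.ncol();
  double entry = -std::log((double) k);
  std::vector<double> fM(k, NEG_INF), fI(k, NEG_INF), fD(k, NEG_INF);
  std::vector<double> pM(k), pI(k), pD(k);
  double total = NEG_INF;
  for (int i = 0; i < L; ++i) {
    pM = fM; pI = fI; pD = fD;
    for (int j = 0; j < k; ++j) {
      double acc = entry;
      if (j > 0 && i > 0) {
        double cont = comb3(pM[j - 1] + lM(j, 0),
                            pI[j - 1] + lI(j, 0),
                            pD[j - 1] + lD(j - 1, 0), viterbi);
        acc = viterbi ? std::max(acc, cont) : logadd(acc, cont);
      }
      fM[j] = em(j, i) + acc;
      fI[j] = (i > 0) ? comb3(pM[j] + lM(j + 1, 1),
                              pI[j] + lI(j + 1, 1),
                              pD[j] + lD(j, 1), viterbi)
                      : NEG_INF;
      fD[j] = (j > 0) ? comb3(fM[j - 1] + lM(j, 2),
                              fI[j - 1] + lI(j, 2),
                              fD[j - 1] + lD(j - 1, 2), viterbi)
                      : NEG_INF;
      total = viterbi ? std::max(total, fM[j]) : logadd(total, fM[j]);
    }
  }
  return total;
}

// Global forward: log P(seq | profile) through the full model
// (begin at position 0, end after position k). lem: k x L match-emission
// log-probabilities; lbg: L insert/background log-probabilities.
// [[Rcpp::export(name = ".profile_forward_global")]]
double profile_forward_global(NumericMatrix lem, NumericVector lbg,
                              NumericMatrix lM, NumericMatrix lI,
                              NumericMatrix lD, bool viterbi) {
  int k = lem.nrow(), L = lem.ncol();
  // fX(j, i): in state X at profile position j having emitted i residues
  NumericMatrix fM(k + 1, L + 1), fI(k + 1, L + 1), fD(k + 1, L + 1);
  std::fill(fM.begin(), fM.end(), NEG_INF);
  std::fill(fI.begin(), fI.end(), NEG_INF);
  std::fill(fD.begin(), fD.end(), NEG_INF);
  fM(0, 0) = 0.0;  // begin state
  for (int i = 0; i <= L; ++i) {
    for (int j = 0; j <= k; ++j) {
      if (j >= 1) {
        if (i >= 1) {
          double d_in = (j >= 2) ? fD(j - 1, i - 1) + lD(j - 2, 0) : NEG_INF;
          fM(j, i) = lem(j - 1, i - 1) +
            comb3(fM(j - 1, i - 1) + lM(j - 1, 0),
                  fI(j - 1, i - 1) + lI(j - 1, 0), d_in, viterbi);
        }
        double d_in = (j >= 2) ? fD(j - 1, i) + lD(j - 2, 2) : NEG_INF;
        fD(j, i) = comb3(fM(j - 1, i) + lM(j - 1, 2),
                         fI(j - 1, i) + lI(j - 1, 2), d_in, viterbi);
      }
      if (i >= 1) {
        double d_in = (j >= 1) ? fD(j, i - 1) + lD(j - 1, 1) : NEG_INF;
        fI(j, i) = lbg[i - 1] +
          comb3(fM(j, i - 1) + lM(j, 1),
                fI(j, i - 1) + lI(j, 1), d_in, viterbi);
      }
    }
  }
  double d_in = (k >= 1) ? fD(k, L) + lD(k - 1, 0) : NEG_INF;
  return comb3(fM(k, L) + lM(k, 0), fI(k, L) + lI(k, 0), d_in, viterbi);
}
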