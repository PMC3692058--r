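#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Inside-outside partition function over pseudoknot-free secondary
// structures with a per-pair Boltzmann weight and minimum hairpin loop of
// three unpaired bases.  The grammar underlying the recursions is the
// unambiguous decomposition
//
//   Z(i,j) = Z(i+1,j) + sum_{k >= i+4} Zb(i,k) * Z(k+1,j)
//   Zb(i,j) = w(i,j) * Z(i+1,j-1)
//
// so that every structure corresponds to exactly one derivation and the
// outside pass yields exact pair and unpaired probabilities in O(n^3).
//
// When close_gu is forbidden, a G-U (or U-G) pair is only admitted when it
// stacks directly on the pair immediately inside it:
//   Zb(i,j) = w(i,j) * Zb(i+1,j-1)        (G-U under no_close_gu)
// This is an inward-stacking approximation of "no G-U at helix ends"; the
// exhaustive enumeration oracle implements the full (either-side) rule.
//
// All tables are kept in long double with a per-base scale factor derived
// from the maximum-weight structure, so sequences of a few thousand
// nucleotides stay in range without log-space arithmetic.

static const int MIN_LOOP = 3; // unpaired bases enclosed by any pair

// [[Rcpp::export]]
List mcc_engine(IntegerVector codes, NumericMatrix pair_weight,
                bool no_close_gu, bool want_matrix) {
  const int n = codes.size();
  if (pair_weight.nrow() != 4 || pair_weight.ncol() != 4)
    stop("pair_weight must be a 4 x 4 matrix");
  for (int i = 0; i < n; ++i)
    if (codes[i] < 0 || codes[i] > 3) stop("sequence codes must be in 0..3");

  const int m = n + 2;
  std::vector<long double> Z((size_t)m * m, 0.0L), Zb((size_t)m * m, 0.0L);
  std::vector<long double> OZ((size_t)m * m, 0.0L), OB((size_t)m * m, 0.0L);
  std::vector<double> lw(16, R_NegInf);
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b)
      if (pair_weight(a, b) > 0.0) lw[4 * a + b] = std::log(pair_weight(a, b));

#define IDX(i, j) ((size_t)(i) * m + (j))
  // empty intervals (j < i) have partition function 1
  for (int i = 0; i <= n + 1; ++i)
    for (int j = 0; j < i && j <= n; ++j) Z[IDX(i, j)] = 1.0L;

  // scale estimate: log-weight of the single best structure (max-plus DP)
  double lambda = 0.0;
  if (n >= 5) {
    std::vector<double> L((size_t)m * m, 0.0), Lb((size_t)m * m, R_NegInf);
    for (int len = 5; len <= n; ++len) {
      for (int i = 1; i + len - 1 <= n; ++i) {
        int j = i + len - 1;
        double lwij = lw[4 * codes[i - 1] + codes[j - 1]];
        if (R_finite(lwij))
          Lb[IDX(i, j)] = lwij + L[IDX(i + 1, j - 1)];
        double best = L[IDX(i + 1, j)];
        for (int k = i + MIN_LOOP + 1; k <= j; ++k) {
          double cand = Lb[IDX(i, k)];
          if (R_finite(cand)) {
            cand += L[IDX(k + 1, j)];
            if (cand > best) best = cand;
          }
        }
        L[IDX(i, j)] = best;
      }
    }
    lambda = L[IDX(1, n)] / n;
  }
  const long double su = std::exp((long double)-lambda);
  const long double spair = su * su;

  // inside pass
  for (int len = 1; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      if (len >= MIN_LOOP + 2) {
        int a = codes[i - 1], b = codes[j - 1];
        double wij = pair_weight(a, b);
        if (wij > 0.0) {
          bool gu = (a == 2 && b == 3) || (a == 3 && b == 2);
          long double inner = (no_close_gu && gu) ? Zb[IDX(i + 1, j - 1)]
                                                  : Z[IDX(i + 1, j - 1)];
          Zb[IDX(i, j)] = (long double)wij * spair * inner;
        }
      }
      long double acc = su * Z[IDX(i + 1, j)];
      for (int k = i + MIN_LOOP + 1; k <= j; ++k)
        acc += Zb[IDX(i, k)] * Z[IDX(k + 1, j)];
      Z[IDX(i, j)] = acc;
    }
  }

  long double Ztot = Z[IDX(1, n)];
  if (!(Ztot > 0.0L) || !std::isfinite((double)std::log(Ztot)))
    stop("partition function under/overflow; sequence too long for the reference engine");

  // outside pass (push-style, intervals by decreasing length)
  OZ[IDX(1, n)] = 1.0L;
  for (int len = n; len >= 1; --len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      long double oz = OZ[IDX(i, j)];
      if (oz != 0.0L) {
        if (i + 1 <= j) OZ[IDX(i + 1, j)] += su * oz;
        for (int k = i + MIN_LOOP + 1; k <= j; ++k) {
          long double zb = Zb[IDX(i, k)];
          if (zb != 0.0L) {
            OB[IDX(i, k)] += oz * Z[IDX(k + 1, j)];
            if (k + 1 <= j) OZ[IDX(k + 1, j)] += oz * zb;
          }
        }
      }
    }
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      long double ob = OB[IDX(i, j)];
      if (ob != 0.0L && len >= MIN_LOOP + 2) {
        int a = codes[i - 1], b = codes[j - 1];
        double wij = pair_weight(a, b);
        if (wij > 0.0) {
          bool gu = (a == 2 && b == 3) || (a == 3 && b == 2);
          long double push = ob * (long double)wij * spair;
          if (no_close_gu && gu)
            OB[IDX(i + 1, j - 1)] += push;
          else
            OZ[IDX(i + 1, j - 1)] += push;
        }
      }
    }
  }

  // unpaired probabilities: mass of the "i unpaired" rule over all contexts
  NumericVector p(n);
  for (int i = 1; i <= n; ++i) {
    long double q = 0.0L;
    for (int j = i; j <= n; ++j) {
      long double oz = OZ[IDX(i, j)];
      if (oz != 0.0L) q += oz * su * Z[IDX(i + 1, j)];
    }
    double qi = (double)(q / Ztot);
    if (qi < 0.0) qi = 0.0;
    if (qi > 1.0) qi = 1.0;
    p[i - 1] = 1.0 - qi;
  }

  double log_z = (double)std::log(Ztot) + lambda * n;
  List out = List::create(Named("p") = p, Named("log_z") = log_z);
  if (want_matrix) {
    NumericMatrix P(n, n);
    for (int i = 1; i <= n; ++i)
      for (int j = i + MIN_LOOP + 1; j <= n; ++j) {
        long double zb = Zb[IDX(i, j)];
        if (zb != 0.0L) {
          double pij = (double)(OB[IDX(i, j)] * zb / Ztot);
          if (pij < 0.0) pij = 0.0;
          if (pij > 1.0) pij = 1.0;
          P(i - 1, j - 1) = pij;
          P(j - 1, i - 1) = pij;
        }
      }
    out["P"] = P;
  }
#undef IDX
  return out;
}
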