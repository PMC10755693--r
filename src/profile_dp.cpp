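#include <Rcpp.h>
using namespace Rcpp;

// Local (Smith-Waterman style) alignment of a position-specific scoring
// profile against a sequence with affine gap penalties.  A gap of length L
// costs gapOpen + L * gapExt.  Profile rows are positions, columns are the
// 20 residues in the package's fixed alphabet order; a residue code of -1
// (unknown, e.g. X) scores 0 at every position.
//
// Returns the best score, the 1-based aligned span on the target, and
// (when traceback is requested) for each profile column the 1-based target
// position aligned to it, or NA when the column is not matched.

// [[Rcpp::export(name = ".profile_local_dp")]]
List profile_local_dp(NumericMatrix prof, IntegerVector seq,
                      double gapOpen, double gapExt, bool traceback) {
  const int L = prof.nrow();      // profile positions
  const int n = seq.size();       // target length
  const double NEG = -1e30;
  const double go = gapOpen + gapExt;   // cost of first gapped position

  double best = 0.0;
  int bi = 0, bj = 0;

  IntegerVector aligned(L, NA_INTEGER);
  int spanStart = NA_INTEGER, spanEnd = NA_INTEGER;

  if (!traceback) {
    // rolling arrays, score only
    std::vector<double> Mprev(n + 1, 0.0), Mcur(n + 1, 0.0);
    std::vector<double> Xprev(n + 1, NEG), Xcur(n + 1, NEG);
    std::vector<double> Yprev(n + 1, NEG), Ycur(n + 1, NEG);
    for (int i = 1; i <= L; ++i) {
      Mcur[0] = 0.0; Xcur[0] = NEG; Ycur[0] = NEG;
      for (int j = 1; j <= n; ++j) {
        const int code = seq[j - 1];
        const double sub = (code >= 0) ? prof(i - 1, code) : 0.0;
        double prev = std::max(Mprev[j - 1],
                               std::max(Xprev[j - 1], Yprev[j - 1]));
        double mval = std::max(0.0, prev + sub);
        Mcur[j] = mval;
        Xcur[j] = std::max(Mprev[j] - go, Xprev[j] - gapExt);
        Ycur[j] = std::max(Mcur[j - 1] - go, Ycur[j - 1] - gapExt);
        if (mval > best) { best = mval; }
      }
      std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
    }
    return List::create(_["score"] = best,
                        _["span_start"] = spanStart,
                        _["span_end"] = spanEnd,
                        _["aligned"] = aligned);
  }

  // full matrices for traceback
  const size_t sz = (size_t)(L + 1) * (n + 1);
  std::vector<double> M(sz, 0.0), X(sz, NEG), Y(sz, NEG);
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

  for (int i = 1; i <= L; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int code = seq[j - 1];
      const double sub = (code >= 0) ? prof(i - 1, code) : 0.0;
      double prev = std::max(M[at(i - 1, j - 1)],
                             std::max(X[at(i - 1, j - 1)],
                                      Y[at(i - 1, j - 1)]));
      double mval = std::max(0.0, prev + sub);
      M[at(i, j)] = mval;
      X[at(i, j)] = std::max(M[at(i - 1, j)] - go,
                             X[at(i - 1, j)] - gapExt);
      Y[at(i, j)] = std::max(M[at(i, j - 1)] - go,
                             Y[at(i, j - 1)] - gapExt);
      if (mval > best) { best = mval; bi = i; bj = j; }
    }
  }

  if (best > 0.0) {
    spanEnd = bj;
    int i = bi, j = bj, state = 1; // 1=M, 2=X (gap in target), 3=Y
    const double eps = 1e-9;
    while (i > 0 && j > 0) {
      if (state == 1) {
        if (M[at(i, j)] <= 0.0) break;   // local alignment start
        aligned[i - 1] = j;
        spanStart = j;
        const int code = seq[j - 1];
        const double sub = (code >= 0) ? prof(i - 1, code) : 0.0;
        const double need = M[at(i, j)] - sub;
        // which predecessor state produced `need`?
        if (std::fabs(M[at(i - 1, j - 1)] - need) < eps ||
            need <= eps) state = 1;
        else if (std::fabs(X[at(i - 1, j - 1)] - need) < eps) state = 2;
        else state = 3;
        --i; --j;
        if (state == 1 && M[at(i, j)] <= eps &&
            std::fabs(need) <= eps) break; // path started here
      } else if (state == 2) {
        const double v = X[at(i, j)];
        state = (std::fabs(M[at(i - 1, j)] - go - v) < eps) ? 1 : 2;
        --i;
      } else {
        const double v = Y[at(i, j)];
        state = (std::fabs(M[at(i, j - 1)] - go - v) < eps) ? 1 : 3;
        --j;
      }
    }
  }

  return List::create(_["score"] = best,
                      _["span_start"] = spanStart,
                      _["span_end"] = spanEnd,
                      _["aligned"] = aligned);
}
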