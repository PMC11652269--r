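#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Optimal local alignment scores under affine gaps (open + k*extend for a
// gap of length k), three-state Smith-Waterman with score floor 0.
// query/subjects hold 0-based indices into the substitution matrix alphabet.
// Scores only: the studentized statistic needs maxima, not tracebacks.
// [[Rcpp::export]]
IntegerVector sw_scores(IntegerVector query, List subjects,
                        IntegerMatrix submat, int gap_open, int gap_extend) {
  const int n = query.size();
  const int nal = submat.nrow();
  if (n == 0) stop("empty query");
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be positive");
  const int goe = gap_open + gap_extend;  // cost of a length-1 gap
  const int NEG = INT_MIN / 4;
  const int *m = INTEGER(submat);
  const int *q = INTEGER(query);
  for (int j = 0; j < n; ++j)
    if (q[j] < 0 || q[j] >= nal) stop("query residue index out of range");

  const int ns = subjects.size();
  IntegerVector out(ns);
  std::vector<int> Hprev(n + 1), Hcur(n + 1), Fcol(n + 1);

  for (int si = 0; si < ns; ++si) {
    IntegerVector subj = subjects[si];
    const int ls = subj.size();
    if (ls == 0) stop("empty subject sequence");
    const int *s = INTEGER(subj);
    std::fill(Hprev.begin(), Hprev.end(), 0);
    std::fill(Fcol.begin(), Fcol.end(), NEG);
    int best = 0;
    for (int i = 1; i <= ls; ++i) {
      const int sres = s[i - 1];
      if (sres < 0 || sres >= nal) stop("subject residue index out of range");
      const int *col = m + (R_xlen_t)sres * nal;
      Hcur[0] = 0;
      int e = NEG;
      for (int j = 1; j <= n; ++j) {
        e = std::max(Hcur[j - 1] - goe, e - gap_extend);
        int f = std::max(Hprev[j] - goe, Fcol[j] - gap_extend);
        Fcol[j] = f;
        int h = Hprev[j - 1] + col[q[j - 1]];
        if (e > h) h = e;
        if (f > h) h = f;
        if (h < 0) h = 0;
        Hcur[j] = h;
        if (h > best) best = h;
      }
      std::swap(Hprev, Hcur);
    }
    out[si] = best;
  }
  return out;
}
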