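#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Three-state Gotoh local alignment with EMBOSS-water gap semantics:
// a gap of length g costs gap_open + (g-1) * gap_ext, charged as gap_open
// on the first gap column and gap_ext on each further column.
//
// Determinism contract:
//  * best cell = highest score; ties broken by smallest tested end
//    coordinate, then smallest aligned end coordinate (row-major scan with
//    strict improvement);
//  * traceback prefers (stop at zero) > diagonal > gap-in-aligned (up) >
//    gap-in-tested (left).
//
// Scores are exact integers; substitution matrix rows/cols follow
// `alphabet` (one char per symbol).

static const int NEG = -1000000000;

// [[Rcpp::export(name = ".gotoh_local")]]
List gotoh_local(std::string tested, std::string aligned,
                 IntegerMatrix submat, std::string alphabet,
                 int gap_open, int gap_ext) {
  const int n = (int) tested.size();
  const int m = (int) aligned.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");

  int map[256];
  for (int i = 0; i < 256; ++i) map[i] = -1;
  for (int k = 0; k < (int) alphabet.size(); ++k)
    map[(unsigned char) alphabet[k]] = k;

  std::vector<int> ti(n), aj(m);
  for (int i = 0; i < n; ++i) {
    int v = map[(unsigned char) tested[i]];
    if (v < 0)
      stop("unsupported symbol '%s' at tested position %d",
           std::string(1, tested[i]).c_str(), i + 1);
    ti[i] = v;
  }
  for (int j = 0; j < m; ++j) {
    int v = map[(unsigned char) aligned[j]];
    if (v < 0)
      stop("unsupported symbol '%s' at aligned position %d",
           std::string(1, aligned[j]).c_str(), j + 1);
    aj[j] = v;
  }

  const int na = (int) alphabet.size();
  std::vector<int> sub((size_t) na * na);
  for (int a = 0; a < na; ++a)
    for (int b = 0; b < na; ++b)
      sub[(size_t) a * na + b] = submat(a, b);

  const int w = m + 1;
  // M: best score of a local alignment ending at (i,j) in a paired column.
  // X: ...ending with a gap column in the aligned sequence (consumes tested).
  // Y: ...ending with a gap column in the tested sequence (consumes aligned).
  std::vector<int> M((size_t)(n + 1) * w, NEG);
  std::vector<int> X((size_t)(n + 1) * w, NEG);
  std::vector<int> Y((size_t)(n + 1) * w, NEG);

  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    const size_t r = (size_t) i * w, rp = (size_t)(i - 1) * w;
    const int tia = ti[i - 1] * na;
    for (int j = 1; j <= m; ++j) {
      const int s = sub[tia + aj[j - 1]];
      int prev = std::max(std::max(M[rp + j - 1], X[rp + j - 1]),
                          Y[rp + j - 1]);
      if (prev < 0) prev = 0;  // fresh local start
      M[r + j] = prev + s;

      const int x1 = (M[rp + j] == NEG) ? NEG : M[rp + j] - gap_open;
      const int x2 = (X[rp + j] == NEG) ? NEG : X[rp + j] - gap_ext;
      X[r + j] = std::max(x1, x2);

      const int y1 = (M[r + j - 1] == NEG) ? NEG : M[r + j - 1] - gap_open;
      const int y2 = (Y[r + j - 1] == NEG) ? NEG : Y[r + j - 1] - gap_ext;
      Y[r + j] = std::max(y1, y2);

      if (M[r + j] > best) { best = M[r + j]; bi = i; bj = j; }
    }
  }

  if (best <= 0) {
    // no positively scoring column anywhere: empty-alignment sentinel
    return List::create(
      _["score"] = 0, _["t_start"] = NA_INTEGER, _["t_end"] = NA_INTEGER,
      _["a_start"] = NA_INTEGER, _["a_end"] = NA_INTEGER,
      _["tested_aln"] = "", _["aligned_aln"] = "",
      _["n_identities"] = 0, _["n_columns"] = 0, _["n_gap_columns"] = 0);
  }

  // traceback
  std::string ta, aa;
  int i = bi, j = bj, nid = 0, ncol = 0, ngap = 0;
  char state = 'M';
  for (;;) {
    const size_t r = (size_t) i * w;
    if (state == 'M') {
      ta.push_back(tested[i - 1]);
      aa.push_back(aligned[j - 1]);
      ++ncol;
      if (tested[i - 1] == aligned[j - 1]) ++nid;
      const int prev = M[r + j] - sub[ti[i - 1] * na + aj[j - 1]];
      --i; --j;
      if (prev <= 0) break;  // local alignment starts here
      const size_t q = (size_t) i * w;
      if (M[q + j] == prev)      state = 'M';
      else if (X[q + j] == prev) state = 'X';
      else if (Y[q + j] == prev) state = 'Y';
      else stop("traceback inconsistency (paired column)");
    } else if (state == 'X') {
      ta.push_back(tested[i - 1]);
      aa.push_back('-');
      ++ncol; ++ngap;
      const int v = X[r + j];
      --i;
      const size_t q = (size_t) i * w;
      if (M[q + j] != NEG && M[q + j] - gap_open == v) state = 'M';
      else if (X[q + j] != NEG && X[q + j] - gap_ext == v) state = 'X';
      else stop("traceback inconsistency (gap in aligned)");
    } else {
      ta.push_back('-');
      aa.push_back(aligned[j - 1]);
      ++ncol; ++ngap;
      const int v = Y[r + j];
      --j;
      if (M[r + j] != NEG && M[r + j] - gap_open == v) state = 'M';
      else if (Y[r + j] != NEG && Y[r + j] - gap_ext == v) state = 'Y';
      else stop("traceback inconsistency (gap in tested)");
    }
  }
  std::reverse(ta.begin(), ta.end());
  std::reverse(aa.begin(), aa.end());

  return List::create(
    _["score"] = best,
    _["t_start"] = i + 1, _["t_end"] = bi,
    _["a_start"] = j + 1, _["a_end"] = bj,
    _["tested_aln"] = ta, _["aligned_aln"] = aa,
    _["n_identities"] = nid, _["n_columns"] = ncol,
    _["n_gap_columns"] = ngap);
}
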