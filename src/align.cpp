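// Banded affine-gap local alignment (Smith-Waterman) used by the
// seed-and-extend homology search. Scoring is supplied by the caller;
// the first base of a gap costs gap_open + gap_ext (so a length-g gap
// costs gap_open + g * gap_ext), matching the convention of the
// Biostrings pairwiseAlignment oracle used in the tests.

#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

namespace {

// traceback codes packed into one byte per cell:
// bits 0-1: H source (0 stop, 1 diag, 2 from E [gap in query], 3 from F)
// bit 2: E extended (gap in query continues)
// bit 3: F extended (gap in subject continues)
const int NEG = -1000000000;

inline int b2i(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return 4; // N and anything else: never matches
  }
}

} // namespace

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string subject,
                  int match, int mismatch, int gap_open, int gap_ext,
                  int diag_lo, int diag_hi) {
  const int m = (int)query.size();
  const int n = (int)subject.size();
  std::vector<int> q(m), s(n);
  for (int i = 0; i < m; ++i) q[i] = b2i(query[i]);
  for (int j = 0; j < n; ++j) s[j] = b2i(subject[j]);

  // diag = j - i in 1-based coordinates; clamp band to feasible range
  if (diag_lo < 1 - m) diag_lo = 1 - m;
  if (diag_hi > n - 1) diag_hi = n - 1;

  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0);
  std::vector<int> Eprev(n + 1, NEG), Ecur(n + 1, NEG); // gap in query (vertical)
  std::vector<int> Fcur(n + 1, NEG);                    // gap in subject (horizontal)
  std::vector<unsigned char> tb((size_t)(m + 1) * (n + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int jlo = diag_lo + i; if (jlo < 1) jlo = 1;
    int jhi = diag_hi + i; if (jhi > n) jhi = n;
    std::fill(Hcur.begin(), Hcur.end(), 0);
    std::fill(Ecur.begin(), Ecur.end(), NEG);
    std::fill(Fcur.begin(), Fcur.end(), NEG);
    if (jlo > jhi) { Hprev.swap(Hcur); Eprev.swap(Ecur); continue; }
    for (int j = jlo; j <= jhi; ++j) {
      unsigned char code = 0;
      // E: gap in query (consume subject? no: consume query base i, gap col)
      // E[i][j]: alignment ends with query i aligned to gap => from row i-1
      int e_open = Hprev[j] - gap_open - gap_ext;
      int e_ext = Eprev[j] - gap_ext;
      int E = e_open >= e_ext ? e_open : e_ext;
      if (e_ext > e_open) code |= 4;
      // F: subject j aligned to gap => from column j-1
      int f_open = Hcur[j - 1] - gap_open - gap_ext;
      int f_ext = Fcur[j - 1] - gap_ext;
      int F = f_open >= f_ext ? f_open : f_ext;
      if (f_ext > f_open) code |= 8;
      int sub = (q[i - 1] < 4 && q[i - 1] == s[j - 1]) ? match : -mismatch;
      int D = Hprev[j - 1] + sub;
      int H = 0; int src = 0;
      if (D > H) { H = D; src = 1; }
      if (E > H) { H = E; src = 2; }
      if (F > H) { H = F; src = 3; }
      code |= (unsigned char)src;
      Hcur[j] = H; Ecur[j] = E; Fcur[j] = F;
      tb[(size_t)i * (n + 1) + j] = code;
      if (H > best) { best = H; bi = i; bj = j; }
    }
    Hprev.swap(Hcur);
    Eprev.swap(Ecur);
  }

  if (best <= 0) {
    return List::create(_["score"] = 0, _["qstart"] = NA_INTEGER,
                        _["qend"] = NA_INTEGER, _["sstart"] = NA_INTEGER,
                        _["send"] = NA_INTEGER, _["nident"] = 0,
                        _["aligned"] = 0);
  }

  // traceback from (bi, bj)
  int i = bi, j = bj;
  int nident = 0, aligned = 0;
  int state = 0; // 0 = in H, 2 = in E, 3 = in F
  while (i > 0 && j > 0) {
    unsigned char code = tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      int src = code & 3;
      if (src == 0) break;
      if (src == 1) {
        ++aligned;
        if (q[i - 1] < 4 && q[i - 1] == s[j - 1]) ++nident;
        --i; --j;
      } else if (src == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      ++aligned;
      bool ext = (code & 4) != 0;
      --i;
      if (!ext) state = 0;
      else {
        // remain in E of the new row; code re-read next loop
      }
    } else {
      ++aligned;
      bool ext = (code & 8) != 0;
      --j;
      if (!ext) state = 0;
    }
  }

  return List::create(_["score"] = best,
                      _["qstart"] = i + 1, _["qend"] = bi,
                      _["sstart"] = j + 1, _["send"] = bj,
                      _["nident"] = nident, _["aligned"] = aligned);
}
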