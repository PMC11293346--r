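#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>

using namespace Rcpp;

// Affine-gap pairwise alignment kernels.
//
// Conventions used throughout:
//  * a gap of length L costs gap_open + L * gap_ext (the opening charge is
//    paid once per gap, every gapped base pays the extension charge) --
//    identical to the Biostrings::pairwiseAlignment convention, which the
//    test suite uses as an independent cross-check;
//  * "semiglobal" means end gaps are free in BOTH sequences (overlap
//    alignment); the reported CIGAR covers only the aligned core and the
//    0-based half-open intervals locate that core on read and reference;
//  * CIGAR ops: M aligned pair (match or mismatch), I read base absent from
//    the reference (insertion), D reference base absent from the read
//    (deletion).  Matches are counted separately so callers can compute
//    identity without re-walking the alignment.

static const int NEG = INT_MIN / 4;

static inline int subst(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

// score-only pass with rolling rows (used for reference pre-selection where
// thousands of alignments are scored and only the winner is traced back)
static int score_pass(const std::string& read, const std::string& ref,
                      int match, int mismatch, int gap_open, int gap_ext,
                      bool local) {
  const int n = (int)read.size(), m = (int)ref.size();
  std::vector<int> Vp(m + 1, 0), Vc(m + 1), Ec(m + 1), Fp(m + 1, NEG);
  int best = local ? 0 : 0; // semiglobal: empty overlap scores 0
  for (int i = 1; i <= n; ++i) {
    Vc[0] = 0; Ec[0] = NEG;
    int Fcj;
    for (int j = 1; j <= m; ++j) {
      int e = std::max(Ec[j - 1] - gap_ext, Vc[j - 1] - gap_open - gap_ext);
      Fcj = std::max(Fp[j] - gap_ext, Vp[j] - gap_open - gap_ext);
      int v = Vp[j - 1] + subst(read[i - 1], ref[j - 1], match, mismatch);
      if (e > v) v = e;
      if (Fcj > v) v = Fcj;
      if (local && v < 0) v = 0;
      Ec[j] = e; Fp[j] = Fcj; Vc[j] = v;
      if (local) { if (v > best) best = v; }
      else if (j == m && v > best) best = v;
    }
    std::swap(Vp, Vc);
  }
  if (!local)
    for (int j = 0; j <= m; ++j) if (Vp[j] > best) best = Vp[j];
  return best;
}

// full pass with traceback; matrices are O(n*m) ints, fine for the
// amplicon-scale sequences this package aligns
static List full_pass(const std::string& read, const std::string& ref,
                      int match, int mismatch, int gap_open, int gap_ext,
                      bool local) {
  const int n = (int)read.size(), m = (int)ref.size();
  const size_t W = (size_t)m + 1;
  std::vector<int> V((size_t)(n + 1) * W, 0), E((size_t)(n + 1) * W, NEG),
      F((size_t)(n + 1) * W, NEG);
  auto at = [W](std::vector<int>& M, int i, int j) -> int& {
    return M[(size_t)i * W + j];
  };
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int e = std::max(at(E, i, j - 1) - gap_ext,
                       at(V, i, j - 1) - gap_open - gap_ext);
      int f = std::max(at(F, i - 1, j) - gap_ext,
                       at(V, i - 1, j) - gap_open - gap_ext);
      int v = at(V, i - 1, j - 1) +
              subst(read[i - 1], ref[j - 1], match, mismatch);
      if (e > v) v = e;
      if (f > v) v = f;
      if (local && v < 0) v = 0;
      at(E, i, j) = e; at(F, i, j) = f; at(V, i, j) = v;
    }
  }
  // locate the alignment end
  int best, bi = 0, bj = 0;
  if (local) {
    best = 0;
    for (int i = 1; i <= n; ++i)
      for (int j = 1; j <= m; ++j)
        if (at(V, i, j) > best) { best = at(V, i, j); bi = i; bj = j; }
  } else {
    best = 0; bi = n; bj = m; best = at(V, n, m);
    for (int j = 0; j <= m; ++j)
      if (at(V, n, j) > best) { best = at(V, n, j); bi = n; bj = j; }
    for (int i = 0; i <= n; ++i)
      if (at(V, i, m) > best) { best = at(V, i, m); bi = i; bj = m; }
  }
  // traceback
  std::vector<std::pair<char, int>> ops;
  auto push_op = [&ops](char op) {
    if (!ops.empty() && ops.back().first == op) ops.back().second++;
    else ops.push_back(std::make_pair(op, 1));
  };
  int i = bi, j = bj, matches = 0, cols = 0, state = 0; // 0=V,1=E,2=F
  while (i > 0 && j > 0) {
    if (state == 0) {
      int v = at(V, i, j);
      if (local && v == 0) break;
      if (v == at(E, i, j)) { state = 1; continue; }
      if (v == at(F, i, j)) { state = 2; continue; }
      push_op('M'); cols++;
      if (read[i - 1] == ref[j - 1] && read[i - 1] != 'N') matches++;
      --i; --j;
    } else if (state == 1) {
      push_op('D'); cols++;
      int cont = (at(E, i, j) == at(E, i, j - 1) - gap_ext);
      --j;
      state = cont ? 1 : 0;
    } else {
      push_op('I'); cols++;
      int cont = (at(F, i, j) == at(F, i - 1, j) - gap_ext);
      --i;
      state = cont ? 2 : 0;
    }
  }
  std::string cigar;
  char buf[16];
  for (auto it = ops.rbegin(); it != ops.rend(); ++it) {
    snprintf(buf, sizeof(buf), "%d%c", it->second, it->first);
    cigar += buf;
  }
  return List::create(
    _["score"] = best,
    _["cigar"] = cigar,
    _["read_start"] = i,  // 0-based start of aligned core on read
    _["read_end"] = bi,   // half-open end
    _["ref_start"] = j,
    _["ref_end"] = bj,
    _["matches"] = matches,
    _["columns"] = cols);
}

// [[Rcpp::export(name = ".cpp_align")]]
List cpp_align(std::string read, std::string ref, int match, int mismatch,
               int gap_open, int gap_ext, bool local, bool score_only) {
  if (score_only)
    return List::create(_["score"] = score_pass(read, ref, match, mismatch,
                                                gap_open, gap_ext, local));
  return full_pass(read, ref, match, mismatch, gap_open, gap_ext, local);
}

// Minimum edit distance (unit-cost substitutions + indels) between a whole
// pattern and ANY substring of the text (infix / "glocal" semantics, the
// natural contract for locating a barcode inside a read end).
// [[Rcpp::export(name = ".cpp_infix_edit")]]
int cpp_infix_edit(std::string pattern, std::string text) {
  const int n = (int)pattern.size(), m = (int)text.size();
  if (n == 0) return 0;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = 0; // free start anywhere in text
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int d = prev[j - 1] + (pattern[i - 1] == text[j - 1] ? 0 : 1);
      int up = prev[j] + 1;      // pattern base unmatched
      int left = cur[j - 1] + 1; // text base unmatched
      cur[j] = d < up ? (d < left ? d : left) : (up < left ? up : left);
    }
    std::swap(prev, cur);
  }
  int best = prev[0];
  for (int j = 1; j <= m; ++j) if (prev[j] < best) best = prev[j];
  return best;
}
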