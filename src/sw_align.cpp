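#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Gotoh local alignment with affine gaps and full traceback.
//
// Conventions (match the R-level contract):
//  - rows index seq_a (the query), columns index seq_b (the target);
//  - a gap of length k costs gap_open + k * gap_extend (both penalties <= 0),
//    i.e. the first gapped base pays gap_open + gap_extend;
//  - 'N' (or any non-ACGT byte) never matches: it always scores `mismatch`;
//  - traceback starts at the maximum-scoring cell (ties: smallest row, then
//    smallest column) and breaks move ties diagonal > up > left, where "up"
//    consumes a query base (CIGAR I) and "left" a target base (CIGAR D
//    relative to the query... see below).  Ops emitted: '=' match,
//    'X' mismatch, 'I' consumes query only, 'D' consumes target only.

static inline int subst(char a, char b, int match, int mismatch) {
  if (a != b) return mismatch;
  switch (a) {
  case 'A': case 'C': case 'G': case 'T': return match;
  default: return mismatch;  // N vs N is still a mismatch
  }
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");
  const long NEG = -1000000000L;
  const int go = gap_open + gap_extend;  // cost of opening (first gapped base)
  const int ge = gap_extend;

  // score matrices, (m+1) x (n+1), row-major
  std::vector<int> H((m + 1) * (n + 1), 0);
  std::vector<int> E((m + 1) * (n + 1), (int)NEG);  // gap in a (left moves)
  std::vector<int> F((m + 1) * (n + 1), (int)NEG);  // gap in b (up moves)
  // traceback: for H, 0=stop, 1=diag, 2=from F(up), 3=from E(left)
  //            for E/F, whether the gap opened at this cell (1) or extends (0)
  std::vector<unsigned char> tbH((m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbE((m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbF((m + 1) * (n + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const char ai = a[i - 1];
    const int row = i * (n + 1), prow = (i - 1) * (n + 1);
    for (int j = 1; j <= n; ++j) {
      // E: gap in a, consumes b[j-1]
      int e_open = H[row + j - 1] + go;
      int e_ext  = E[row + j - 1] + ge;
      if (e_open >= e_ext) { E[row + j] = e_open; tbE[row + j] = 1; }
      else                 { E[row + j] = e_ext;  tbE[row + j] = 0; }
      // F: gap in b, consumes a[i-1]
      int f_open = H[prow + j] + go;
      int f_ext  = F[prow + j] + ge;
      if (f_open >= f_ext) { F[row + j] = f_open; tbF[row + j] = 1; }
      else                 { F[row + j] = f_ext;  tbF[row + j] = 0; }
      // H: priority diag > up(F) > left(E) > stop, highest score wins
      int diag = H[prow + j - 1] + subst(ai, b[j - 1], match, mismatch);
      int h = 0; unsigned char t = 0;
      if (diag > 0) { h = diag; t = 1; }
      if (F[row + j] > h) { h = F[row + j]; t = 2; }
      if (E[row + j] > h) { h = E[row + j]; t = 3; }
      H[row + j] = h; tbH[row + j] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback from (bi, bj), state H
  std::string ops;  // reversed during walk
  int i = bi, j = bj;
  char state = 'H';
  while (i > 0 && j > 0) {
    int idx = i * (n + 1) + j;
    if (state == 'H') {
      unsigned char t = tbH[idx];
      if (t == 0) break;
      if (t == 1) {
        ops.push_back(subst(a[i - 1], b[j - 1], 1, -1) > 0 ? '=' : 'X');
        --i; --j;
      } else if (t == 2) {
        state = 'F';
      } else {
        state = 'E';
      }
    } else if (state == 'F') {  // up: consumes a
      ops.push_back('I');
      if (tbF[idx]) state = 'H';
      --i;
    } else {                    // left: consumes b
      ops.push_back('D');
      if (tbE[idx]) state = 'H';
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());

  // run-length encode and collect mismatch columns
  std::vector<std::string> op_chr;
  std::vector<int> op_len;
  std::vector<int> mm_a, mm_b;        // 1-based positions in a and b
  std::vector<std::string> mm_a_base, mm_b_base;
  int pa = i, pb = j;                 // 0-based consumed counts so far
  int n_match = 0, n_mismatch = 0, n_gap = 0;
  for (size_t k = 0; k < ops.size(); ++k) {
    char op = ops[k];
    if (op_chr.empty() || op_chr.back()[0] != op) {
      op_chr.push_back(std::string(1, op));
      op_len.push_back(1);
    } else {
      op_len.back()++;
    }
    if (op == '=' || op == 'X') {
      if (op == 'X') {
        mm_a.push_back(pa + 1); mm_b.push_back(pb + 1);
        mm_a_base.push_back(std::string(1, a[pa]));
        mm_b_base.push_back(std::string(1, b[pb]));
        ++n_mismatch;
      } else ++n_match;
      ++pa; ++pb;
    } else if (op == 'I') { ++pa; ++n_gap; }
    else { ++pb; ++n_gap; }
  }

  return List::create(
    _["score"] = best,
    _["a_start"] = i + 1, _["a_end"] = bi,   // 1-based inclusive, empty if start>end
    _["b_start"] = j + 1, _["b_end"] = bj,
    _["op"] = op_chr, _["len"] = op_len,
    _["n_match"] = n_match, _["n_mismatch"] = n_mismatch,
    _["n_gap_bases"] = n_gap,
    _["mm_a_pos"] = mm_a, _["mm_b_pos"] = mm_b,
    _["mm_a_base"] = mm_a_base, _["mm_b_base"] = mm_b_base);
}
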