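// Banded ends-free global alignment with affine gaps, plus pileup counting.
//
// The aligner is the workhorse of the whole pipeline: reads are full-length
// copies of a linearized plasmid, so a global alignment with free end gaps
// (no penalty for unaligned leading/trailing stretches of either sequence)
// is the right model, and a narrow band around the main diagonal is enough.
// The band grows adaptively: if the optimal path touches the band edge the
// alignment is recomputed with a doubled band, up to the configured maximum.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cstring>
using namespace Rcpp;

static const int NEG = -1000000000;

// base codes: A=1 C=2 G=3 T=4, N (or anything else) = 5.
// 0 is reserved for gaps in the column representation, so N must not
// collide with it; N never matches anything, including another N.
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 1;
  case 'C': return 2;
  case 'G': return 3;
  case 'T': return 4;
  default:  return 5;
  }
}

struct AlnResult {
  int score;
  bool saturated;
  // column representation: ref code (0 = gap) / read code (0 = gap),
  // plus read index per column (-1 for deletion columns)
  std::vector<int> acol, bcol, bidx;
  int ref_start, ref_end; // 0-based half-open span of ref covered by aligned cols
};

// One banded DP run with half-width w. Returns false only on internal error.
static bool run_band(const std::vector<int>& ref, const std::vector<int>& rd,
                     int w, int match, int mismatch, int gap_open, int gap_extend,
                     AlnResult& out) {
  const int m = (int)ref.size();   // columns j = 0..m
  const int n = (int)rd.size();    // rows    i = 0..n
  const int d = m - n;
  const int lo = std::min(0, d) - w;
  const int hi = std::max(0, d) + w;
  const int W = hi - lo + 1;

  std::vector<int> M((size_t)(n + 1) * W, NEG), X((size_t)(n + 1) * W, NEG),
      Y((size_t)(n + 1) * W, NEG);
  // traceback: for M which predecessor state (0=M,1=X,2=Y); for X 0=M,1=X; Y 0=M,2=Y
  std::vector<unsigned char> tM((size_t)(n + 1) * W, 0), tX((size_t)(n + 1) * W, 0),
      tY((size_t)(n + 1) * W, 0);

  const int ge = gap_extend, go = gap_open;

  auto IDX = [&](int i, int j) { return (size_t)i * W + (j - i - lo); };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= m && j - i >= lo && j - i <= hi;
  };

  // free leading gaps: row 0 (ref skipped) and column 0 (read overhang)
  for (int j = std::max(0, lo); j <= std::min(m, hi); ++j) M[IDX(0, j)] = 0;
  for (int i = 0; i <= n; ++i) if (inband(i, 0)) M[IDX(i, 0)] = 0;

  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(1, i + lo), jhi = std::min(m, i + hi);
    for (int j = jlo; j <= jhi; ++j) {
      size_t here = IDX(i, j);
      // M: diagonal move
      if (inband(i - 1, j - 1)) {
        size_t dg = IDX(i - 1, j - 1);
        int best = M[dg]; unsigned char who = 0;
        if (X[dg] > best) { best = X[dg]; who = 1; }
        if (Y[dg] > best) { best = Y[dg]; who = 2; }
        if (best > NEG / 2) {
          int sub = (ref[j - 1] <= 4 && ref[j - 1] == rd[i - 1]) ? match : mismatch;
          M[here] = best + sub; tM[here] = who;
        }
      }
      // X: gap in read (deletion, consumes ref base j)
      if (j - 1 - i >= lo) { // (i, j-1) in band (j-1 >= 0 given j >= 1)
        size_t lf = IDX(i, j - 1);
        int fromM = (M[lf] > NEG / 2) ? M[lf] + go + ge : NEG;
        int fromX = (X[lf] > NEG / 2) ? X[lf] + ge : NEG;
        if (fromM >= fromX) { if (fromM > NEG / 2) { X[here] = fromM; tX[here] = 0; } }
        else { X[here] = fromX; tX[here] = 1; }
      }
      // Y: gap in ref (insertion, consumes read base i)
      if (j - (i - 1) <= hi) { // (i-1, j) in band
        size_t up = IDX(i - 1, j);
        int fromM = (M[up] > NEG / 2) ? M[up] + go + ge : NEG;
        int fromY = (Y[up] > NEG / 2) ? Y[up] + ge : NEG;
        if (fromM >= fromY) { if (fromM > NEG / 2) { Y[here] = fromM; tY[here] = 0; } }
        else { Y[here] = fromY; tY[here] = 2; }
      }
    }
  }

  // free trailing gaps: best over last row (any j) and last column (any i)
  int bi = -1, bj = -1, bstate = 0, bscore = NEG;
  for (int j = std::max(0, n + lo); j <= std::min(m, n + hi); ++j) {
    size_t c = IDX(n, j);
    if (M[c] > bscore) { bscore = M[c]; bi = n; bj = j; bstate = 0; }
    if (X[c] > bscore) { bscore = X[c]; bi = n; bj = j; bstate = 1; }
    if (Y[c] > bscore) { bscore = Y[c]; bi = n; bj = j; bstate = 2; }
  }
  for (int i = 0; i <= n; ++i) {
    if (!inband(i, m)) continue;
    size_t c = IDX(i, m);
    if (M[c] > bscore) { bscore = M[c]; bi = i; bj = m; bstate = 0; }
    if (X[c] > bscore) { bscore = X[c]; bi = i; bj = m; bstate = 1; }
    if (Y[c] > bscore) { bscore = Y[c]; bi = i; bj = m; bstate = 2; }
  }
  if (bi < 0) return false;

  // traceback
  std::vector<int> acol, bcol, bidx; // reversed
  bool saturated = false;
  int i = bi, j = bj, st = bstate;
  int end_i = bi, end_j = bj;
  while (i > 0 && j > 0) {
    int k = j - i - lo;
    if ((k == 0 || k == hi - lo) && j > 0 && j < m) saturated = true;
    size_t c = IDX(i, j);
    if (st == 0) {
      if (M[c] == 0 && (tM[c] == 0) && !(inband(i - 1, j - 1) &&
          (M[IDX(i - 1, j - 1)] > NEG / 2))) break; // degenerate; shouldn't happen
      unsigned char who = tM[c];
      acol.push_back(ref[j - 1]); bcol.push_back(rd[i - 1]); bidx.push_back(i - 1);
      --i; --j; st = who;
      // stop if we've reached a free-start cell
      if ((i == 0 || j == 0) ) break;
      // if predecessor M cell holds 0 because it is a free start on row0/col0
      // the loop condition handles it next round
    } else if (st == 1) {
      acol.push_back(ref[j - 1]); bcol.push_back(0); bidx.push_back(-1);
      unsigned char who = tX[c];
      --j; st = (who == 0) ? 0 : 1;
    } else {
      acol.push_back(0); bcol.push_back(rd[i - 1]); bidx.push_back(i - 1);
      unsigned char who = tY[c];
      --i; st = (who == 0) ? 0 : 2;
    }
  }
  int start_i = i, start_j = j;

  // leading free gaps: read overhang becomes insertion columns at the start
  // (only possible when start_j == 0); skipped ref is simply uncovered.
  std::vector<int> A, B, BI;
  A.reserve(acol.size() + start_i + (rd.size() - end_i));
  if (start_j == 0) {
    for (int t = 0; t < start_i; ++t) { A.push_back(0); B.push_back(rd[t]); BI.push_back(t); }
  }
  for (int t = (int)acol.size() - 1; t >= 0; --t) {
    A.push_back(acol[t]); B.push_back(bcol[t]); BI.push_back(bidx[t]);
  }
  // trailing read overhang (only when end_j == m)
  if (end_j == m) {
    for (int t = end_i; t < n; ++t) { A.push_back(0); B.push_back(rd[t]); BI.push_back(t); }
  }

  out.score = bscore;
  out.saturated = saturated;
  out.acol = std::move(A);
  out.bcol = std::move(B);
  out.bidx = std::move(BI);
  out.ref_start = (start_j == 0) ? 0 : start_j;
  out.ref_end = end_j;
  // when traceback stopped inside (start_j>0), ref_start = start_j; recompute:
  out.ref_start = start_j;
  return true;
}

// Left-normalize gaps: shift every insertion/deletion run to its leftmost
// score-equivalent placement (standard homopolymer convention).
static void left_align(std::vector<int>& A, std::vector<int>& B, std::vector<int>& BI) {
  const int L = (int)A.size();
  bool changed = true;
  while (changed) {
    changed = false;
    int c = 0;
    while (c < L) {
      if (A[c] == 0 || B[c] == 0) {
        bool ins = (A[c] == 0);
        int s = c, e = c;
        while (e + 1 < L && ((ins && A[e + 1] == 0) || (!ins && B[e + 1] == 0))) ++e;
        // shift run [s..e] left while the preceding column is aligned and
        // the rotated base matches
        while (s > 0 && A[s - 1] != 0 && B[s - 1] != 0) {
          if (ins) {
            if (B[e] != B[s - 1] || B[e] == 0) break;
            A[e] = A[s - 1]; A[s - 1] = 0;
            // read bases/indices stay put: column s-1 becomes insertion of its
            // read base, column e becomes aligned
          } else {
            if (A[e] != A[s - 1]) break;
            B[e] = B[s - 1]; BI[e] = BI[s - 1];
            B[s - 1] = 0; BI[s - 1] = -1;
          }
          --s; --e; changed = true;
        }
        c = e + 1;
      } else ++c;
    }
  }
}

// [[Rcpp::export]]
List cpp_align(std::string ref, std::string read, int band_width,
               int match, int mismatch, int gap_open, int gap_extend) {
  std::vector<int> rf(ref.size()), rd(read.size());
  for (size_t t = 0; t < ref.size(); ++t) rf[t] = base_code(ref[t]);
  for (size_t t = 0; t < read.size(); ++t) rd[t] = base_code(read[t]);
  const int m = (int)rf.size(), n = (int)rd.size();
  if (m == 0 || n == 0) stop("empty sequence in alignment");

  int wmax = std::max(2, band_width / 2);
  // small problems get the full band at once: exact unbanded behaviour
  bool small = (long long)(m + 1) * (n + 1) <= 45000;
  int w = small ? std::max(wmax, m + n) : std::min(wmax, 16);
  if (small) wmax = w;
  AlnResult res;
  bool ok = false;
  while (true) {
    ok = run_band(rf, rd, w, match, mismatch, gap_open, gap_extend, res);
    if (!ok) stop("alignment failed internally");
    if (!res.saturated || w >= wmax) break;
    w = std::min(wmax, w * 2);
  }

  left_align(res.acol, res.bcol, res.bidx);

  // emit ops: 1=match 2=mismatch 3=insertion 4=deletion
  int L = (int)res.acol.size();
  std::vector<int> op(L), ref_pos(L), base(L), read_pos(L);
  int j = res.ref_start; // 0-based ref index of next aligned ref base
  int match_count = 0;
  int ref_start = -1, ref_end = -1;
  for (int c = 0; c < L; ++c) {
    if (res.acol[c] != 0 && res.bcol[c] != 0) {
      bool is_match = (res.acol[c] == res.bcol[c] && res.acol[c] <= 4);
      op[c] = is_match ? 1 : 2;
      ref_pos[c] = j;
      base[c] = (res.bcol[c] == 5) ? 0 : res.bcol[c];
      read_pos[c] = res.bidx[c];
      if (is_match) ++match_count;
      if (ref_start < 0) ref_start = j;
      ref_end = j + 1;
      ++j;
    } else if (res.bcol[c] == 0) { // deletion (ref base missing from read)
      op[c] = 4; ref_pos[c] = j; base[c] = 0; read_pos[c] = -1;
      if (ref_start < 0) ref_start = j;
      ref_end = j + 1;
      ++j;
    } else { // insertion: junction index = next ref base position
      op[c] = 3; ref_pos[c] = j;
      base[c] = (res.bcol[c] == 5) ? 0 : res.bcol[c];
      read_pos[c] = res.bidx[c];
    }
  }
  if (ref_start < 0) { ref_start = res.ref_start; ref_end = res.ref_start; }

  return List::create(
    _["score"] = res.score,
    _["match_count"] = match_count,
    _["ref_start"] = ref_start,
    _["ref_end"] = ref_end,
    _["band_saturated"] = res.saturated,
    _["op"] = IntegerVector(op.begin(), op.end()),
    _["ref_pos"] = IntegerVector(ref_pos.begin(), ref_pos.end()),
    _["base"] = IntegerVector(base.begin(), base.end()),
    _["read_pos"] = IntegerVector(read_pos.begin(), read_pos.end()));
}

// Pileup accumulation over a draft of length L.
// alignments: list of lists with elements op, ref_pos, base, ref_start, ref_end
// [[Rcpp::export]]
List cpp_pileup(List alignments, int L) {
  IntegerMatrix base_counts(5, L); // rows: A,C,G,T,gap
  std::vector<int> span(L + 1, 0), with_ins(L + 1, 0);
  std::map<long long, int> ins; // key = ((junction * 64) + offset) * 5 + base

  const int MAXOFF = 63;
  for (int r = 0; r < alignments.size(); ++r) {
    List a = alignments[r];
    IntegerVector op = a["op"], ref_pos = a["ref_pos"], base = a["base"];
    int rs = as<int>(a["ref_start"]), re = as<int>(a["ref_end"]);
    if (re > L || rs < 0) stop("alignment outside draft coordinates");

    int jlo = (rs == 0) ? 0 : rs + 1;
    int jhi = (re == L) ? L : re - 1;
    for (int j = jlo; j <= jhi; ++j) span[j] += 1;

    int cur_j = -1, offset = 0;
    std::vector<int> seen_junction;
    for (int c = 0; c < op.size(); ++c) {
      int o = op[c], p = ref_pos[c], b = base[c];
      if (o == 1 || o == 2) {
        if (p < 0 || p >= L) stop("alignment outside draft coordinates");
        if (b != 0) base_counts(b - 1, p) += 1;
        cur_j = -1;
      } else if (o == 4) {
        if (p < 0 || p >= L) stop("alignment outside draft coordinates");
        base_counts(4, p) += 1;
        cur_j = -1;
      } else { // insertion at junction p (0..L)
        if (p < 0 || p > L) stop("alignment outside draft coordinates");
        if (p == cur_j) ++offset; else { cur_j = p; offset = 0; }
        if (b != 0) {
          int off = std::min(offset, MAXOFF);
          ins[((long long)p * (MAXOFF + 1) + off) * 5 + b] += 1;
          bool seen = false;
          for (int t = 0; t < (int)seen_junction.size(); ++t)
            if (seen_junction[t] == p) { seen = true; break; }
          if (!seen) { seen_junction.push_back(p); with_ins[p] += 1; }
        }
      }
    }
  }

  int K = (int)ins.size();
  IntegerVector ij(K), io(K), ib(K), ic(K);
  int t = 0;
  for (std::map<long long, int>::iterator it = ins.begin(); it != ins.end(); ++it, ++t) {
    long long key = it->first;
    ib[t] = (int)(key % 5);
    long long rest = key / 5;
    io[t] = (int)(rest % 64);
    ij[t] = (int)(rest / 64);
    ic[t] = it->second;
  }
  IntegerVector sp(span.begin(), span.end()), wi(with_ins.begin(), with_ins.end());
  return List::create(
    _["base_counts"] = base_counts,
    _["span"] = sp,
    _["with_ins"] = wi,
    _["ins_junction"] = ij,
    _["ins_offset"] = io,
    _["ins_base"] = ib,
    _["ins_count"] = ic);
}
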