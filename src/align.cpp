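#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh) with optional banding around a centre
// diagonal d0 (allowed cells satisfy |(j - i) - d0| <= band, with 0-based i
// over the query and j over the target).  Traceback yields a SAM-style CIGAR
// over {M,I,D}: I consumes query, D consumes target.
//
// Tie-break, applied in order: highest score, smallest target start of the
// optimal path, smallest query start.  Path starts are propagated through the
// DP so ties are resolved exactly.

namespace {

const int32_t NEG = INT32_MIN / 4;

struct Cell {
  int32_t h, e, f;          // H / gap-consuming-target (E) / gap-consuming-query (F)
  int32_t oq_h, ot_h;       // origin (query, target start) of each path
  int32_t oq_e, ot_e;
  int32_t oq_f, ot_f;
};

inline Cell neutral_cell() {
  Cell c;
  c.h = 0; c.e = NEG; c.f = NEG;
  c.oq_h = c.ot_h = c.oq_e = c.ot_e = c.oq_f = c.ot_f = 0;
  return c;
}

inline bool better_origin(int32_t ot_new, int32_t oq_new,
                          int32_t ot_old, int32_t oq_old) {
  if (ot_new != ot_old) return ot_new < ot_old;
  return oq_new < oq_old;
}

} // namespace

// [[Rcpp::export(name = ".cpp_local_align")]]
List cpp_local_align(std::string q, std::string t,
                     int match, int mismatch, int gap_open, int gap_extend,
                     int band, int d0) {
  const int n = (int)q.size();
  const int m = (int)t.size();
  List empty = List::create(
      _["score"] = 0, _["qstart"] = 0, _["qend"] = 0,
      _["tstart"] = 0, _["tend"] = 0, _["cigar"] = "",
      _["matches"] = 0, _["block_length"] = 0);
  if (n == 0 || m == 0) return empty;

  const bool banded = band >= 0;
  auto jlo = [&](int i) {
    if (!banded) return 0;
    int lo = i + d0 - band;
    return lo < 0 ? 0 : lo;
  };
  auto jhi = [&](int i) {
    if (!banded) return m - 1;
    int hi = i + d0 + band;
    return hi > m - 1 ? m - 1 : hi;
  };
  const int width = banded ? (2 * band + 1) : m;
  if ((double)n * (double)width > 6e8)
    stop("alignment problem too large; supply a band");

  // traceback byte: bits 0-1 H source (0 stop, 1 diag, 2 E, 3 F);
  // bit 2: E extended an E run; bit 3: F extended an F run
  std::vector<uint8_t> tb((size_t)n * (size_t)width, 0);
  auto tbi = [&](int i, int j) -> uint8_t& {
    int col = banded ? (j - (i + d0 - band)) : j;
    return tb[(size_t)i * (size_t)width + (size_t)col];
  };

  std::vector<Cell> prev((size_t)m, neutral_cell());
  std::vector<Cell> cur((size_t)m, neutral_cell());

  int32_t best = 0;
  int bi = -1, bj = -1;
  int32_t b_ot = INT32_MAX, b_oq = INT32_MAX;

  for (int i = 0; i < n; ++i) {
    const int lo = jlo(i), hi = jhi(i);
    for (int j = lo; j <= hi; ++j) {
      Cell c = neutral_cell();
      uint8_t dir = 0;

      if (j - 1 >= lo) {               // E from left neighbour (same row)
        const Cell &L = cur[(size_t)(j - 1)];
        int32_t open = L.h + gap_open;
        int32_t ext  = (L.e <= NEG / 2) ? NEG : L.e + gap_extend;
        if (ext > open) { c.e = ext; c.oq_e = L.oq_e; c.ot_e = L.ot_e; dir |= 4; }
        else if (open > NEG / 2) { c.e = open; c.oq_e = L.oq_h; c.ot_e = L.ot_h; }
      }
      if (i > 0 && j >= jlo(i - 1) && j <= jhi(i - 1)) {  // F from upper neighbour
        const Cell &U = prev[(size_t)j];
        int32_t open = U.h + gap_open;
        int32_t ext  = (U.f <= NEG / 2) ? NEG : U.f + gap_extend;
        if (ext > open) { c.f = ext; c.oq_f = U.oq_f; c.ot_f = U.ot_f; dir |= 8; }
        else if (open > NEG / 2) { c.f = open; c.oq_f = U.oq_h; c.ot_f = U.ot_h; }
      }

      // H: diagonal step (extends a positive path or starts fresh here)
      const int32_t s = (q[(size_t)i] == t[(size_t)j]) ? match : mismatch;
      int32_t diag; int32_t d_oq = i, d_ot = j;
      if (i > 0 && j - 1 >= jlo(i - 1) && j - 1 <= jhi(i - 1) &&
          prev[(size_t)(j - 1)].h > 0) {
        diag = prev[(size_t)(j - 1)].h + s;
        d_oq = prev[(size_t)(j - 1)].oq_h;
        d_ot = prev[(size_t)(j - 1)].ot_h;
      } else {
        diag = s;
      }

      int32_t h = 0; int src = 0; int32_t oq = i, ot = j;
      if (diag > 0) { h = diag; src = 1; oq = d_oq; ot = d_ot; }
      if (c.e > h || (c.e == h && c.e > 0 &&
                      better_origin(c.ot_e, c.oq_e, ot, oq))) {
        h = c.e; src = 2; oq = c.oq_e; ot = c.ot_e;
      }
      if (c.f > h || (c.f == h && c.f > 0 &&
                      better_origin(c.ot_f, c.oq_f, ot, oq))) {
        h = c.f; src = 3; oq = c.oq_f; ot = c.ot_f;
      }
      c.h = h; c.oq_h = oq; c.ot_h = ot;
      dir |= (uint8_t)src;
      tbi(i, j) = dir;
      cur[(size_t)j] = c;

      if (h > best ||
          (h == best && h > 0 &&
           (better_origin(ot, oq, b_ot, b_oq) ||
            (ot == b_ot && oq == b_oq && (j < bj || (j == bj && i < bi)))))) {
        best = h; bi = i; bj = j; b_ot = ot; b_oq = oq;
      }
    }
    std::swap(prev, cur);
    if (banded && i + 1 < n) {
      // neutralize cells that enter the band at row i+1 but were not
      // computed at row i (they hold stale values from older rows)
      const int nlo = jlo(i + 1), nhi = jhi(i + 1);
      for (int j = nlo; j <= nhi; ++j)
        if (j < lo || j > hi) prev[(size_t)j] = neutral_cell();
    }
  }

  if (best <= 0) return empty;

  // traceback
  std::string ops; ops.reserve(256);
  int i = bi, j = bj, matches = 0;
  int state = 0;  // 0 = H, 2 = inside an E run, 3 = inside an F run
  while (i >= 0 && j >= 0) {
    if (state == 0) {
      if (banded && (j < jlo(i) || j > jhi(i))) break;  // fresh start at band edge
      int src = tbi(i, j) & 3;
      if (src == 0) break;
      if (src == 1) {
        ops.push_back('M');
        if (q[(size_t)i] == t[(size_t)j]) ++matches;
        --i; --j;
      } else {
        state = src;  // enter gap run at this cell, no move yet
      }
    } else if (state == 2) {
      ops.push_back('D');
      const bool ext = (tbi(i, j) & 4) != 0;
      --j;
      if (!ext) state = 0;
    } else {
      ops.push_back('I');
      const bool ext = (tbi(i, j) & 8) != 0;
      --i;
      if (!ext) state = 0;
    }
  }
  const int qstart = i + 1, tstart = j + 1;

  std::string cigar; cigar.reserve(64);
  int blen = 0;
  for (size_t k = ops.size(); k > 0; ) {
    const char op = ops[k - 1];
    size_t run = 0;
    while (k > 0 && ops[k - 1] == op) { --k; ++run; }
    blen += (int)run;
    cigar += std::to_string(run);
    cigar.push_back(op);
  }
  return List::create(_["score"] = best,
                      _["qstart"] = qstart, _["qend"] = bi + 1,
                      _["tstart"] = tstart, _["tend"] = bj + 1,
                      _["cigar"] = cigar,
                      _["matches"] = matches, _["block_length"] = blen);
}
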