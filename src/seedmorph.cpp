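#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// 8-connected component labelling of a logical mask (row-major scan order).
// Labels are assigned 1..k in order of first encounter, so label order is
// deterministic and translation-stable.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(256);
  int next = 0;
  static const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) && lab(r, c) == 0) {
        ++next;
        lab(r, c) = next;
        stack.clear();
        stack.push_back(r * nc + c);
        while (!stack.empty()) {
          int idx = stack.back();
          stack.pop_back();
          int cr = idx / nc, cc = idx % nc;
          for (int k = 0; k < 8; ++k) {
            int rr = cr + dr[k], ccol = cc + dc[k];
            if (rr >= 0 && rr < nr && ccol >= 0 && ccol < nc &&
                mask(rr, ccol) && lab(rr, ccol) == 0) {
              lab(rr, ccol) = next;
              stack.push_back(rr * nc + ccol);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Moore-neighbour boundary trace of one labelled region (outer boundary,
// clockwise, Jacob's stopping criterion). Returns an n x 2 matrix of
// 1-based (row, col) coordinates.
// [[Rcpp::export(name = ".cpp_trace_boundary")]]
IntegerMatrix cpp_trace_boundary(IntegerMatrix lab, int label) {
  int nr = lab.nrow(), nc = lab.ncol();
  int sr = -1, sc = -1;
  for (int r = 0; r < nr && sr < 0; ++r)
    for (int c = 0; c < nc; ++c)
      if (lab(r, c) == label) { sr = r; sc = c; break; }
  if (sr < 0) return IntegerMatrix(0, 2);

  // clockwise Moore neighbourhood starting from W
  static const int mr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  static const int mc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};

  std::vector<int> rows, cols;
  rows.push_back(sr); cols.push_back(sc);

  // the tracer's state is (position, next-move direction): the walk is
  // deterministic given that pair, so returning to the start pixel about
  // to repeat the very first move closes the loop exactly
  int cr = sr, cc = sc;
  int prevFound = -1, firstMove = -1;
  long maxSteps = 4L * nr * nc + 8L; // safety net
  for (long step = 0; step < maxSteps; ++step) {
    // scan order guarantees the W neighbour of the start is background,
    // so the initial backtrack direction is W
    int backtrack = (prevFound < 0) ? 0 : (prevFound + 5) % 8;
    int found = -1;
    for (int t = 0; t < 8; ++t) {
      int kk = (backtrack + t) % 8;
      int rr = cr + mr[kk], ccn = cc + mc[kk];
      if (rr >= 0 && rr < nr && ccn >= 0 && ccn < nc && lab(rr, ccn) == label) {
        found = kk;
        break;
      }
    }
    if (found < 0) break;                       // isolated pixel
    if (firstMove < 0) firstMove = found;
    else if (cr == sr && cc == sc && found == firstMove) break;
    cr += mr[found]; cc += mc[found];
    rows.push_back(cr); cols.push_back(cc);
    prevFound = found;
  }
  // drop the duplicated start produced by the closing re-entry
  if (rows.size() > 1 && rows.back() == sr && cols.back() == sc) {
    rows.pop_back(); cols.pop_back();
  }

  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i] + 1;
    out(i, 1) = cols[i] + 1;
  }
  return out;
}

// Grayscale dilation with a square structuring element of odd side k,
// repeated iter times. Separable max filter (rows then columns) per pass.
// [[Rcpp::export(name = ".cpp_dilate")]]
IntegerMatrix cpp_dilate(IntegerMatrix img, int k, int iter) {
  int nr = img.nrow(), nc = img.ncol();
  int half = k / 2;
  IntegerMatrix cur = clone(img);
  if (iter == 0 || k == 1) return cur;
  IntegerMatrix tmp(nr, nc);
  for (int it = 0; it < iter; ++it) {
    // horizontal pass
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) {
        int lo = c - half < 0 ? 0 : c - half;
        int hi = c + half >= nc ? nc - 1 : c + half;
        int m = cur(r, lo);
        for (int j = lo + 1; j <= hi; ++j)
          if (cur(r, j) > m) m = cur(r, j);
        tmp(r, c) = m;
      }
    }
    // vertical pass
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        int lo = r - half < 0 ? 0 : r - half;
        int hi = r + half >= nr ? nr - 1 : r + half;
        int m = tmp(lo, c);
        for (int i = lo + 1; i <= hi; ++i)
          if (tmp(i, c) > m) m = tmp(i, c);
        cur(r, c) = m;
      }
    }
  }
  return cur;
}

// CRC-32 (IEEE 802.3, as used by PNG chunks) of a raw vector.
// [[Rcpp::export(name = ".cpp_crc32")]]
double cpp_crc32(RawVector x) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t n = 0; n < 256; ++n) {
      uint32_t c = n;
      for (int kk = 0; kk < 8; ++kk)
        c = (c & 1) ? 0xedb88320u ^ (c >> 1) : c >> 1;
      table[n] = c;
    }
    init = true;
  }
  uint32_t crc = 0xffffffffu;
  for (R_xlen_t i = 0; i < x.size(); ++i)
    crc = table[(crc ^ x[i]) & 0xffu] ^ (crc >> 8);
  return (double)(crc ^ 0xffffffffu);
}
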