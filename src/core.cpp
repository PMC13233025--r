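#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

const double TWO_PI = 6.283185307179586476925286766559;

struct QEntry {
  double q;
  int r, c;     // 0-based position of the pixel to unwrap
  int pr, pc;   // predecessor (already unwrapped)
};

// priority_queue pops the "largest": highest quality first, ties broken
// lexicographically by (row, col), smaller first, for determinism.
struct QLess {
  bool operator()(const QEntry &a, const QEntry &b) const {
    if (a.q != b.q) return a.q < b.q;
    if (a.r != b.r) return a.r > b.r;
    return a.c > b.c;
  }
};

} // namespace

//' @name unwrap_qg_cpp
//' @keywords internal
// [[Rcpp::export(name = ".unwrap_qg_cpp")]]
NumericMatrix unwrap_qg_cpp(NumericMatrix wrapped, NumericMatrix quality) {
  const int nr = wrapped.nrow(), nc = wrapped.ncol();
  if (quality.nrow() != nr || quality.ncol() != nc)
    stop("wrapped phase and quality map must have identical dimensions");

  NumericMatrix out(nr, nc);
  std::vector<char> visited(static_cast<size_t>(nr) * nc, 0);

  // seed: global quality maximum, ties lexicographic (row, col)
  int sr = 0, sc = 0;
  double qmax = R_NegInf;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double q = quality(r, c);
      if (q > qmax || (q == qmax && (r < sr || (r == sr && c < sc)))) {
        qmax = q; sr = r; sc = c;
      }
    }

  std::priority_queue<QEntry, std::vector<QEntry>, QLess> pq;
  out(sr, sc) = wrapped(sr, sc);
  visited[static_cast<size_t>(sc) * nr + sr] = 1;

  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  for (int k = 0; k < 4; ++k) {
    int r = sr + dr[k], c = sc + dc[k];
    if (r >= 0 && r < nr && c >= 0 && c < nc)
      pq.push(QEntry{quality(r, c), r, c, sr, sc});
  }

  while (!pq.empty()) {
    QEntry e = pq.top();
    pq.pop();
    size_t idx = static_cast<size_t>(e.c) * nr + e.r;
    if (visited[idx]) continue;
    double w = wrapped(e.r, e.c);
    double ref = out(e.pr, e.pc);
    double k2pi = std::round((ref - w) / TWO_PI);
    out(e.r, e.c) = w + TWO_PI * k2pi;
    visited[idx] = 1;
    for (int k = 0; k < 4; ++k) {
      int r = e.r + dr[k], c = e.c + dc[k];
      if (r >= 0 && r < nr && c >= 0 && c < nc &&
          !visited[static_cast<size_t>(c) * nr + r])
        pq.push(QEntry{quality(r, c), r, c, e.r, e.c});
    }
  }
  return out;
}

//' @name label8_cpp
//' @keywords internal
// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc); // zero-initialized
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int k = 0; k < 8; ++k) {
          int rr = p.first + dr[k], cc = p.second + dc[k];
          if (rr >= 0 && rr < nr && cc >= 0 && cc < nc &&
              mask(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  return lab;
}

//' @name inpaint_nearest_cpp
//' @keywords internal
// [[Rcpp::export(name = ".inpaint_nearest_cpp")]]
NumericMatrix inpaint_nearest_cpp(NumericMatrix x, LogicalMatrix object) {
  const int nr = x.nrow(), nc = x.ncol();
  if (object.nrow() != nr || object.ncol() != nc)
    stop("raster and object mask must have identical dimensions");
  NumericMatrix out = clone(x);
  std::vector<char> filled(static_cast<size_t>(nr) * nc, 0);
  std::queue<std::pair<int, int> > q;
  bool any_bg = false;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (!object(r, c)) {
        filled[static_cast<size_t>(c) * nr + r] = 1;
        q.push(std::make_pair(r, c));
        any_bg = true;
      }
  if (!any_bg) stop("object mask covers the whole raster; nothing to inpaint from");
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!q.empty()) {
    std::pair<int, int> p = q.front();
    q.pop();
    for (int k = 0; k < 8; ++k) {
      int rr = p.first + dr[k], cc = p.second + dc[k];
      if (rr >= 0 && rr < nr && cc >= 0 && cc < nc &&
          !filled[static_cast<size_t>(cc) * nr + rr]) {
        out(rr, cc) = out(p.first, p.second);
        filled[static_cast<size_t>(cc) * nr + rr] = 1;
        q.push(std::make_pair(rr, cc));
      }
    }
  }
  return out;
}
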