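#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Connected-component labeling of a binary matrix. Labels are assigned in
// raster-scan order (column-major storage, but scan proceeds row-by-row so
// the first pixel of component k precedes the first pixel of k+1).
// connectivity is 4 or 8.
// [[Rcpp::export(name = ".cpp_label")]]
IntegerMatrix cpp_label(const IntegerMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> qr(H * (size_t)W), qc(H * (size_t)W);
  const int dr4[] = {-1, 1, 0, 0},  dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nd = (connectivity == 8) ? 8 : 4;
  int next = 0;
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      int head = 0, tail = 0;
      qr[tail] = i; qc[tail] = j; ++tail;
      lab(i, j) = next;
      while (head < tail) {
        int r = qr[head], c = qc[head]; ++head;
        for (int d = 0; d < nd; ++d) {
          int rr = r + dr[d], cc = c + dc[d];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            qr[tail] = rr; qc[tail] = cc; ++tail;
          }
        }
      }
    }
  }
  return lab;
}

// Joint spatial-range mean-shift filtering of a single-channel plane with a
// flat (uniform) kernel. For each pixel the estimate (x, y, v) is moved to
// the mean of the original samples lying within Chebyshev spatial distance
// hs of (x, y) and within hr of v, for at most maxIters iterations or until
// the intensity shift drops below tol. The output pixel takes the converged
// intensity.
// [[Rcpp::export(name = ".cpp_mean_shift")]]
NumericMatrix cpp_mean_shift(const NumericMatrix& plane, int hs, double hr,
                             int maxIters, double tol) {
  const int H = plane.nrow(), W = plane.ncol();
  NumericMatrix out(H, W);
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      double cy = i, cx = j, cv = plane(i, j);
      for (int it = 0; it < maxIters; ++it) {
        int r0 = (int)std::ceil(cy - hs);  if (r0 < 0) r0 = 0;
        int r1 = (int)std::floor(cy + hs); if (r1 > H - 1) r1 = H - 1;
        int c0 = (int)std::ceil(cx - hs);  if (c0 < 0) c0 = 0;
        int c1 = (int)std::floor(cx + hs); if (c1 > W - 1) c1 = W - 1;
        double sy = 0.0, sx = 0.0, sv = 0.0;
        int k = 0;
        for (int r = r0; r <= r1; ++r) {
          for (int c = c0; c <= c1; ++c) {
            double v = plane(r, c);
            if (std::fabs(v - cv) <= hr) {
              sy += r; sx += c; sv += v; ++k;
            }
          }
        }
        if (k == 0) break;
        double nv = sv / k;
        double shift = std::fabs(nv - cv);
        cy = sy / k; cx = sx / k; cv = nv;
        if (shift < tol) break;
      }
      out(i, j) = cv;
    }
  }
  return out;
}

struct FloodNode {
  double height;
  long seq;
  int idx;
  int label;
};
struct FloodCmp {
  bool operator()(const FloodNode& a, const FloodNode& b) const {
    if (a.height != b.height) return a.height > b.height; // min-heap on height
    return a.seq > b.seq;                                 // then FIFO
  }
};

// Marker-controlled watershed by priority flooding. `surface` is the
// topographic relief (flooded from low to high), `markers` holds positive
// seed labels, `domain` restricts flooding (pixels outside stay 0).
// 4-connected. Ties in height are broken by insertion order, which makes the
// partition fully deterministic; ridge pixels are claimed by the basin that
// reaches them first.
// [[Rcpp::export(name = ".cpp_marked_watershed")]]
IntegerMatrix cpp_marked_watershed(const NumericMatrix& surface,
                                   const IntegerMatrix& markers,
                                   const LogicalMatrix& domain) {
  const int H = surface.nrow(), W = surface.ncol();
  IntegerMatrix lab(H, W);
  std::priority_queue<FloodNode, std::vector<FloodNode>, FloodCmp> pq;
  long seq = 0;
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j)
      if (domain(i, j) && markers(i, j) > 0) {
        lab(i, j) = markers(i, j);
        pq.push(FloodNode{surface(i, j), seq++, i + j * H, markers(i, j)});
      }
  const int dr[] = {-1, 1, 0, 0}, dc[] = {0, 0, -1, 1};
  while (!pq.empty()) {
    FloodNode nd = pq.top(); pq.pop();
    int r = nd.idx % H, c = nd.idx / H;
    for (int d = 0; d < 4; ++d) {
      int rr = r + dr[d], cc = c + dc[d];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      if (!domain(rr, cc) || lab(rr, cc) != 0) continue;
      lab(rr, cc) = nd.label;
      pq.push(FloodNode{surface(rr, cc), seq++, rr + cc * H, nd.label});
    }
  }
  return lab;
}

// Moore-neighbour boundary tracing of one 4-connected piece starting at its
// first raster pixel. Returns the chain-code length with diagonal steps
// weighted sqrt(2). A single isolated pixel has no chain and contributes the
// unit-perimeter convention handled by the caller.
static double trace_piece(const IntegerMatrix& lab, int piece, int si, int sj) {
  const int H = lab.nrow(), W = lab.ncol();
  // clockwise order starting north
  const int dr[] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[] = {0, 1, 1, 1, 0, -1, -1, -1};
  // direction from current pixel back to the previous backtrack pixel;
  // the start pixel is the first in raster order so its west neighbour is
  // background: backtrack direction = 6 (west).
  int cr = si, cj = sj, bdir = 6;
  double per = 0.0;
  int firstMove = -1;
  long guard = 0, cap = 8L * H * W + 16;
  while (true) {
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      int d = (bdir + k) % 8;
      int rr = cr + dr[d], cc = cj + dc[d];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      if (lab(rr, cc) == piece) { found = d; break; }
    }
    if (found < 0) return 0.0; // isolated pixel
    bool diag = (found % 2) == 1;
    per += diag ? std::sqrt(2.0) : 1.0;
    int nr = cr + dr[found], nc = cj + dc[found];
    // backtrack direction of the new pixel points to the neighbour we
    // examined just before the found one
    int prev = (found + 7) % 8;
    // express the pixel at direction `prev` from (cr,cj) as a direction from
    // (nr,nc): recompute by scanning
    int br = cr + dr[prev], bc = cj + dc[prev];
    int nb = 6;
    for (int d = 0; d < 8; ++d)
      if (nr + dr[d] == br && nc + dc[d] == bc) { nb = d; break; }
    cr = nr; cj = nc; bdir = nb;
    if (firstMove < 0) firstMove = found;
    // Jacob's stopping criterion: back at the start about to repeat
    if (cr == si && cj == sj) {
      // peek at the next move
      int nxt = -1;
      for (int k = 1; k <= 8; ++k) {
        int d = (bdir + k) % 8;
        int rr = cr + dr[d], cc = cj + dc[d];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (lab(rr, cc) == piece) { nxt = d; break; }
      }
      if (nxt == firstMove || nxt < 0) break;
    }
    if (++guard > cap) break;
  }
  return per;
}

// Chain-code perimeter per label. Labels need not be 4-connected (watershed
// output): each 4-connected piece is traced separately and the lengths are
// summed. Isolated single pixels contribute 1 by convention.
// [[Rcpp::export(name = ".cpp_chain_perimeter")]]
NumericVector cpp_chain_perimeter(const IntegerMatrix& labels, int nlab) {
  const int H = labels.nrow(), W = labels.ncol();
  NumericVector per(nlab);
  // split every label into 4-connected pieces
  IntegerMatrix bin(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j)
      bin(i, j) = labels(i, j) > 0 ? 1 : 0;
  // piece ids must not merge across different labels: label pieces within
  // the masked label image directly
  IntegerMatrix piece(H, W);
  int np = 0;
  std::vector<int> pr, pc, powner;
  std::vector<int> qr(H * (size_t)W), qc(H * (size_t)W);
  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      if (labels(i, j) == 0 || piece(i, j) != 0) continue;
      ++np;
      int lb = labels(i, j);
      pr.push_back(i); pc.push_back(j); powner.push_back(lb);
      int head = 0, tail = 0;
      qr[tail] = i; qc[tail] = j; ++tail;
      piece(i, j) = np;
      while (head < tail) {
        int r = qr[head], c = qc[head]; ++head;
        for (int d = 0; d < 4; ++d) {
          int rr = r + dr4[d], cc = c + dc4[d];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (labels(rr, cc) == lb && piece(rr, cc) == 0) {
            piece(rr, cc) = np;
            qr[tail] = rr; qc[tail] = cc; ++tail;
          }
        }
      }
    }
  for (int p = 0; p < np; ++p) {
    double len = trace_piece(piece, p + 1, pr[p], pc[p]);
    if (len <= 0.0) len = 1.0; // single-pixel convention
    int owner = powner[p];
    if (owner >= 1 && owner <= nlab) per[owner - 1] += len;
  }
  return per;
}
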