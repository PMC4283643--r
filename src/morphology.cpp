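#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 8-connected component labelling of a binary mask by breadth-first search.
// Returns an integer matrix with 0 = background, 1..n = component id.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> qr, qc;
  qr.reserve(1024); qc.reserve(1024);
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      qr.clear(); qc.clear();
      qr.push_back(i); qc.push_back(j);
      size_t head = 0;
      while (head < qr.size()) {
        int r = qr[head], c = qc[head]; ++head;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              qr.push_back(rr); qc.push_back(cc);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Two-pass 3-4 chamfer distance transform (approximate Euclidean distance,
// in pixels, of each foreground pixel to the nearest background pixel).
// [[Rcpp::export]]
NumericMatrix cpp_chamfer_distance(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double BIG = 1e12, A = 3.0, B = 4.0;
  NumericMatrix d(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      d(i, j) = mask(i, j) ? BIG : 0.0;
  // forward pass
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (d(i, j) == 0.0) continue;
      double v = d(i, j);
      if (i > 0)            v = std::min(v, d(i - 1, j) + A);
      if (j > 0)            v = std::min(v, d(i, j - 1) + A);
      if (i > 0 && j > 0)   v = std::min(v, d(i - 1, j - 1) + B);
      if (i < nr - 1 && j > 0) v = std::min(v, d(i + 1, j - 1) + B);
      d(i, j) = v;
    }
  }
  // backward pass
  for (int j = nc - 1; j >= 0; --j) {
    for (int i = nr - 1; i >= 0; --i) {
      if (d(i, j) == 0.0) continue;
      double v = d(i, j);
      if (i < nr - 1)             v = std::min(v, d(i + 1, j) + A);
      if (j < nc - 1)             v = std::min(v, d(i, j + 1) + A);
      if (i < nr - 1 && j < nc - 1) v = std::min(v, d(i + 1, j + 1) + B);
      if (i > 0 && j < nc - 1)    v = std::min(v, d(i - 1, j + 1) + B);
      d(i, j) = v;
    }
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (d(i, j) > 0.0) d(i, j) /= A;  // scale so unit step costs 1 px
  return d;
}

struct PixNode {
  double dist; int order; int r, c, marker;
};
struct PixCmp {
  // max-heap on distance; FIFO tie-break for determinism
  bool operator()(const PixNode& a, const PixNode& b) const {
    if (a.dist != b.dist) return a.dist < b.dist;
    return a.order > b.order;
  }
};

// Marker-based watershed used to split touching somata. Within each
// connected component of `labels`, local maxima of the distance transform
// are found, maxima closer than min_peak_dist are merged (keeping the
// higher), and if more than one marker survives the component is flooded
// in order of decreasing distance, each pixel joining the marker basin it
// is first reached from. Components with a single marker are unchanged.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed_split(const NumericMatrix& dist,
                                  const IntegerMatrix& labels,
                                  double min_peak_dist) {
  const int nr = dist.nrow(), nc = dist.ncol();
  int ncomp = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      ncomp = std::max(ncomp, labels(i, j));
  if (ncomp == 0) return clone(labels);

  // collect local maxima (8-neighbourhood, plateau pixels all qualify)
  std::vector<std::vector<int> > maxr(ncomp + 1), maxc(ncomp + 1);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int L = labels(i, j);
      if (L == 0) continue;
      double v = dist(i, j);
      bool is_max = true;
      for (int dr = -1; dr <= 1 && is_max; ++dr) {
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          int rr = i + dr, cc = j + dc;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (labels(rr, cc) == L && dist(rr, cc) > v) { is_max = false; break; }
        }
      }
      if (is_max) { maxr[L].push_back(i); maxc[L].push_back(j); }
    }
  }

  IntegerMatrix out(nr, nc);
  std::priority_queue<PixNode, std::vector<PixNode>, PixCmp> pq;
  int order = 0, next_marker = 0;
  const double d2min = min_peak_dist * min_peak_dist;

  for (int L = 1; L <= ncomp; ++L) {
    size_t nm = maxr[L].size();
    if (nm == 0) continue;
    // greedy non-maximum suppression: sort candidate maxima by distance
    // value (desc), keep those farther than min_peak_dist from any kept
    std::vector<size_t> idx(nm);
    for (size_t k = 0; k < nm; ++k) idx[k] = k;
    std::stable_sort(idx.begin(), idx.end(), [&](size_t a, size_t b) {
      double da = dist(maxr[L][a], maxc[L][a]);
      double db = dist(maxr[L][b], maxc[L][b]);
      if (da != db) return da > db;
      if (maxc[L][a] != maxc[L][b]) return maxc[L][a] < maxc[L][b];
      return maxr[L][a] < maxr[L][b];
    });
    std::vector<int> kr, kc;
    for (size_t k = 0; k < nm; ++k) {
      int r = maxr[L][idx[k]], c = maxc[L][idx[k]];
      bool keep = true;
      for (size_t m = 0; m < kr.size(); ++m) {
        double dr = r - kr[m], dc = c - kc[m];
        if (dr * dr + dc * dc < d2min) { keep = false; break; }
      }
      if (keep) { kr.push_back(r); kc.push_back(c); }
    }
    if (kr.size() == 1) {
      // single soma: keep the whole component as one basin
      ++next_marker;
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i)
          if (labels(i, j) == L) out(i, j) = next_marker;
      continue;
    }
    for (size_t m = 0; m < kr.size(); ++m) {
      ++next_marker;
      out(kr[m], kc[m]) = next_marker;
      pq.push(PixNode{dist(kr[m], kc[m]), order++, kr[m], kc[m], next_marker});
    }
  }

  // priority flood, constrained to stay within the original component
  while (!pq.empty()) {
    PixNode n = pq.top(); pq.pop();
    int L = labels(n.r, n.c);
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        if (dr == 0 && dc == 0) continue;
        int rr = n.r + dr, cc = n.c + dc;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (labels(rr, cc) != L || out(rr, cc) != 0) continue;
        out(rr, cc) = n.marker;
        pq.push(PixNode{dist(rr, cc), order++, rr, cc, n.marker});
      }
    }
  }
  return out;
}
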