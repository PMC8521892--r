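#include <Rcpp.h>
using namespace Rcpp;

// 8-connected component labelling of a logical mask, two-pass union-find.
// Labels are 1..k in first-encounter (column-major) order of their roots.

static int find_root(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// [[Rcpp::export]]
IntegerMatrix label_components_8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  int next = 1;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int best = 0;
      // neighbours already visited in column-major order:
      // (i-1, j), (i-1, j-1), (i, j-1), (i+1, j-1)
      const int di[4] = {-1, -1, 0, 1};
      const int dj[4] = {0, -1, -1, -1};
      int neigh[4], nn = 0;
      for (int q = 0; q < 4; ++q) {
        int ni = i + di[q], nj = j + dj[q];
        if (ni < 0 || ni >= nr || nj < 0) continue;
        int l = lab(ni, nj);
        if (l > 0) {
          int r = find_root(parent, l);
          neigh[nn++] = r;
          if (best == 0 || r < best) best = r;
        }
      }
      if (best == 0) {
        parent.push_back(next);
        lab(i, j) = next++;
      } else {
        lab(i, j) = best;
        for (int q = 0; q < nn; ++q) parent[neigh[q]] = best;
      }
    }
  }

  // flatten and relabel compactly in order of first appearance
  std::vector<int> newlab(next, 0);
  int k = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = find_root(parent, l);
      if (newlab[r] == 0) newlab[r] = ++k;
      lab(i, j) = newlab[r];
    }
  return lab;
}
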