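#include <Rcpp.h>
using namespace Rcpp;

// 8-connected component labelling of a logical/numeric matrix (non-zero =
// foreground). Two-pass union-find; labels are 1..n in first-encounter
// (column-major) order, background stays 0.

static int find_root(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void unite(std::vector<int>& parent, int a, int b) {
  a = find_root(parent, a);
  b = find_root(parent, b);
  if (a != b) parent[std::max(a, b)] = std::min(a, b);
}

// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(LogicalMatrix x) {
  const int H = x.nrow(), W = x.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  int next = 1;

  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!x(r, c)) continue;
      // previously visited 8-neighbours in column-major scan order
      int best = 0;
      int nb[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
      for (int k = 0; k < 4; ++k) {
        int rr = nb[k][0], cc = nb[k][1];
        if (rr < 0 || rr >= H || cc < 0) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(parent, best, l);
          if (l < best) best = l;
        }
      }
      if (best == 0) {
        parent.push_back(next);
        best = next++;
      }
      lab(r, c) = best;
    }
  }

  // resolve + relabel compactly in first-encounter order
  std::vector<int> remap(next, 0);
  int out = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = find_root(parent, l);
      if (remap[root] == 0) remap[root] = ++out;
      lab(r, c) = remap[root];
    }
  return lab;
}
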