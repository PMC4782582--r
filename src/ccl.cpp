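#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra < rb) parent[rb] = ra; else if (rb < ra) parent[ra] = rb;
}

// Two-pass connected-component labeling of a logical matrix.
// First pass scans in raster order (row-major over the image), assigns
// provisional labels from already-visited neighbors and records label
// equivalences in a union-find forest; second pass resolves equivalences.
// Final labels are renumbered 1..n in raster order of each component's
// first pixel. connectivity is 4 or 8.
// [[Rcpp::export(name = ".cpp_label_twopass")]]
IntegerMatrix cpp_label_twopass(LogicalMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);  // parent[0] unused
  int next_label = 1;

  // neighbor offsets that precede the current pixel in raster order
  // raster order: rows within a row... we scan r fastest? Use row-major
  // (r = row index, scan rows top to bottom, cols left to right):
  // previous neighbors: (r, c-1), (r-1, c), and for 8-connectivity
  // (r-1, c-1), (r-1, c+1).
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c)) continue;
      int best = 0;
      int neigh[4][2] = {{r, c - 1}, {r - 1, c}, {r - 1, c - 1}, {r - 1, c + 1}};
      int nn = (connectivity == 8) ? 4 : 2;
      for (int k = 0; k < nn; ++k) {
        int rr = neigh[k][0], cc = neigh[k][1];
        if (rr < 0 || cc < 0 || cc >= W) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          if (best == 0) best = l;
          else if (l != best) uf_union(parent, best, l);
        }
      }
      if (best == 0) {
        best = next_label++;
        parent.push_back(best);
      }
      lab(r, c) = best;
    }
  }

  // resolve equivalences and renumber 1..n in raster order of first pixel
  std::vector<int> newlab(next_label, 0);
  int n_final = 0;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = uf_find(parent, l);
      if (newlab[root] == 0) newlab[root] = ++n_final;
      lab(r, c) = newlab[root];
    }
  }
  return lab;
}

// For each point (rows a/cols a), the minimum Euclidean distance to the
// point set b. Coordinates are numeric (row, col) pairs.
// [[Rcpp::export(name = ".cpp_min_dist")]]
NumericVector cpp_min_dist(NumericVector ar, NumericVector ac,
                           NumericVector br, NumericVector bc) {
  int na = ar.size(), nb = br.size();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double dr = ar[i] - br[j], dc = ac[i] - bc[j];
      double d2 = dr * dr + dc * dc;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
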