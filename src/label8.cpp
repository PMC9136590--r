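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
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

//' Label connected components of a binary mask (8-connectivity)
//'
//' Two-pass union-find labelling. Foreground pixels (non-zero) that touch
//' through any of the 8 neighbours belong to the same component, so thin
//' diagonal worm bodies stay connected. Labels are positive integers in
//' raster-scan discovery order; background is 0.
//'
//' @param mask integer or logical matrix; non-zero is foreground.
//' @return integer matrix of the same shape with component labels.
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix label_components8(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(1024);
  parent.push_back(0); // label 0 = background sentinel

  // pass 1: provisional labels, merging with the 4 already-seen neighbours
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0) continue;
      int best = 0;
      int neigh[4];
      int nn = 0;
      if (r > 0 && lab(r - 1, c)) neigh[nn++] = lab(r - 1, c);
      if (c > 0) {
        if (lab(r, c - 1)) neigh[nn++] = lab(r, c - 1);
        if (r > 0 && lab(r - 1, c - 1)) neigh[nn++] = lab(r - 1, c - 1);
        if (r + 1 < nr && lab(r + 1, c - 1)) neigh[nn++] = lab(r + 1, c - 1);
      }
      for (int k = 0; k < nn; ++k)
        if (best == 0 || neigh[k] < best) best = neigh[k];
      if (best == 0) {
        int fresh = (int)parent.size();
        parent.push_back(fresh);
        lab(r, c) = fresh;
      } else {
        lab(r, c) = best;
        for (int k = 0; k < nn; ++k) uf_union(parent, best, neigh[k]);
      }
    }
  }

  // pass 2: resolve to compact labels in first-appearance order
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = uf_find(parent, l);
      if (remap[root] == 0) remap[root] = ++next;
      lab(r, c) = remap[root];
    }
  }
  return lab;
}

//' Per-label exposed perimeter (4-neighbour edge count)
//'
//' Counts, for every labelled component, the number of pixel edges shared
//' with background or with the image border. This is the rasterised
//' perimeter used by the compactness and spot-ring scores.
//'
//' @param lab integer label matrix from [label_components8()].
//' @param nlab number of labels.
//' @return integer vector of length `nlab`.
//' @keywords internal
// [[Rcpp::export]]
IntegerVector label_perimeter(const IntegerMatrix& lab, const int nlab) {
  const int nr = lab.nrow(), nc = lab.ncol();
  IntegerVector per(nlab);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const int l = lab(r, c);
      if (l == 0) continue;
      if (r == 0 || lab(r - 1, c) != l) ++per[l - 1];
      if (r == nr - 1 || lab(r + 1, c) != l) ++per[l - 1];
      if (c == 0 || lab(r, c - 1) != l) ++per[l - 1];
      if (c == nc - 1 || lab(r, c + 1) != l) ++per[l - 1];
    }
  }
  return per;
}
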