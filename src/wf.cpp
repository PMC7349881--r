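#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Copy one meiotic product of parent haplotypes (rows hp1, hp2 of `src`)
// into row `dst_row` of `dst`. Crossovers are a Poisson process along the
// genetic map `pos_m` (positions in Morgans); the starting haplotype is
// chosen at random. Uses R's RNG so results are governed by set.seed().
static void meiosis(const IntegerMatrix& src, int hp1, int hp2,
                    IntegerMatrix& dst, int dst_row,
                    const NumericVector& pos_m, double map_len) {
  int S = pos_m.size();
  int nx = (map_len > 0.0) ? (int) R::rpois(map_len) : 0;
  int cur = (unif_rand() < 0.5) ? 0 : 1;
  if (nx == 0) {
    int row = cur == 0 ? hp1 : hp2;
    for (int s = 0; s < S; s++) dst(dst_row, s) = src(row, s);
    return;
  }
  std::vector<double> cuts(nx);
  for (int i = 0; i < nx; i++) cuts[i] = unif_rand() * map_len;
  std::sort(cuts.begin(), cuts.end());
  int ci = 0;
  for (int s = 0; s < S; s++) {
    while (ci < nx && pos_m[s] > cuts[ci]) { cur ^= 1; ci++; }
    dst(dst_row, s) = cur == 0 ? src(hp1, s) : src(hp2, s);
  }
}

// Evolve a diploid Wright-Fisher population forward in time.
// haps: per-chromosome IntegerMatrix of 2*N0 haplotype rows (rows 2i, 2i+1
//       belong to individual i), alleles coded 0/1 (or arbitrary integer
//       labels, e.g. founder-origin ids).
// pos_m: per-chromosome SNP positions in Morgans.
// n_per_gen: population size at each generation to simulate (length = number
//       of generations); parents are drawn uniformly, distinct (no selfing).
// [[Rcpp::export]]
List wf_evolve_cpp(List haps, List pos_m, IntegerVector n_per_gen) {
  int C = haps.size();
  std::vector<IntegerMatrix> cur(C), nxt(C);
  std::vector<NumericVector> pos(C);
  std::vector<double> maplen(C);
  int n_cur = 0;
  int n_max = 0;
  for (int g = 0; g < n_per_gen.size(); g++)
    if (n_per_gen[g] > n_max) n_max = n_per_gen[g];
  for (int c = 0; c < C; c++) {
    IntegerMatrix h = haps[c];
    pos[c] = as<NumericVector>(pos_m[c]);
    maplen[c] = pos[c].size() ? pos[c][pos[c].size() - 1] : 0.0;
    n_cur = h.nrow() / 2;
    int rows = 2 * std::max(n_max, n_cur);
    cur[c] = IntegerMatrix(rows, h.ncol());
    nxt[c] = IntegerMatrix(rows, h.ncol());
    for (int i = 0; i < h.nrow(); i++)
      for (int s = 0; s < h.ncol(); s++) cur[c](i, s) = h(i, s);
  }
  if (n_cur < 2) stop("need at least 2 founders");
  for (int g = 0; g < n_per_gen.size(); g++) {
    int n_next = n_per_gen[g];
    if (n_next < 2) stop("population size must be at least 2");
    for (int j = 0; j < n_next; j++) {
      int p1 = (int)(unif_rand() * n_cur);
      if (p1 >= n_cur) p1 = n_cur - 1;
      int p2 = p1;
      while (p2 == p1) {
        p2 = (int)(unif_rand() * n_cur);
        if (p2 >= n_cur) p2 = n_cur - 1;
      }
      for (int c = 0; c < C; c++) {
        meiosis(cur[c], 2 * p1, 2 * p1 + 1, nxt[c], 2 * j, pos[c], maplen[c]);
        meiosis(cur[c], 2 * p2, 2 * p2 + 1, nxt[c], 2 * j + 1, pos[c], maplen[c]);
      }
    }
    for (int c = 0; c < C; c++) std::swap(cur[c], nxt[c]);
    n_cur = n_next;
  }
  List out(C);
  for (int c = 0; c < C; c++) {
    IntegerMatrix res(2 * n_cur, cur[c].ncol());
    for (int i = 0; i < 2 * n_cur; i++)
      for (int s = 0; s < cur[c].ncol(); s++) res(i, s) = cur[c](i, s);
    out[c] = res;
  }
  return out;
}

// One gamete from a parent's two haplotype rows (vectors), with origins
// carried along. Returns a 2-row matrix: row 0 alleles, row 1 origins.
// [[Rcpp::export]]
IntegerMatrix gamete_cpp(IntegerVector al1, IntegerVector al2,
                         IntegerVector or1, IntegerVector or2,
                         NumericVector pos_m) {
  int S = al1.size();
  IntegerMatrix out(2, S);
  double L = S ? pos_m[S - 1] : 0.0;
  int nx = (L > 0.0) ? (int) R::rpois(L) : 0;
  int cur = (unif_rand() < 0.5) ? 0 : 1;
  std::vector<double> cuts(nx);
  for (int i = 0; i < nx; i++) cuts[i] = unif_rand() * L;
  std::sort(cuts.begin(), cuts.end());
  int ci = 0;
  for (int s = 0; s < S; s++) {
    while (ci < nx && pos_m[s] > cuts[ci]) { cur ^= 1; ci++; }
    out(0, s) = cur == 0 ? al1[s] : al2[s];
    out(1, s) = cur == 0 ? or1[s] : or2[s];
  }
  return out;
}
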