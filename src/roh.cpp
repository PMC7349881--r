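#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Consecutive-runs ROH scan over one individual's dosages on one chromosome.
// d: dosages 0/1/2, NA = missing; pos: base-pair positions (sorted
// ascending). A run opens on a homozygous call and extends right; one
// heterozygote and one missing call (configurable) may be absorbed; a gap
// larger than max_gap_bp between consecutive SNPs, or an allowance overflow,
// closes the run at the last homozygous call (so runs start and end on
// homozygous evidence). Closed runs are kept iff they span at least
// min_length_bp and contain at least min_snps SNPs. Scanning resumes at the
// SNP after the violation (at the right-hand SNP for a gap violation).
// Returns a matrix with columns: start_idx, end_idx (1-based), n_snps,
// n_het, n_missing.
// [[Rcpp::export]]
IntegerMatrix roh_scan_cpp(IntegerVector d, NumericVector pos,
                           double max_gap_bp, int max_het, int max_missing,
                           double min_length_bp, int min_snps) {
  int S = d.size();
  std::vector<int> rows;
  int i = 0;
  while (i < S) {
    if (d[i] == NA_INTEGER || d[i] == 1) { i++; continue; }
    int last_hom = i, nhet = 0, nmiss = 0;
    int k = i + 1;
    int resume = S;
    while (k < S) {
      if (pos[k] - pos[k - 1] > max_gap_bp) { resume = k; break; }
      if (d[k] == 1) {
        if (++nhet > max_het) { resume = k + 1; break; }
      } else if (d[k] == NA_INTEGER) {
        if (++nmiss > max_missing) { resume = k + 1; break; }
      } else {
        last_hom = k;
      }
      k++;
    }
    // trimmed run [i, last_hom]
    if (last_hom > i &&
        pos[last_hom] - pos[i] >= min_length_bp &&
        last_hom - i + 1 >= min_snps) {
      int nh = 0, nm = 0;
      for (int s = i; s <= last_hom; s++) {
        if (d[s] == 1) nh++;
        else if (d[s] == NA_INTEGER) nm++;
      }
      rows.push_back(i + 1);
      rows.push_back(last_hom + 1);
      rows.push_back(last_hom - i + 1);
      rows.push_back(nh);
      rows.push_back(nm);
    }
    i = (k >= S) ? S : resume;
  }
  int nr = rows.size() / 5;
  IntegerMatrix out(nr, 5);
  for (int r = 0; r < nr; r++)
    for (int c = 0; c < 5; c++) out(r, c) = rows[5 * r + c];
  colnames(out) = CharacterVector::create("start_idx", "end_idx", "n_snps",
                                          "n_het", "n_missing");
  return out;
}
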