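#include <Rcpp.h>
using namespace Rcpp;

// Greedy methylation-homogeneity segmentation over the CpG index.
// B: n x G matrix of pooled per-group betas (NA = no coverage);
// pos: 0-based CpG positions; chrom_id: integer chromosome codes.
// A block grows while its bp span stays within max_bp and every group's
// within-block beta range stays within tau. Returns 1-based block start
// indices.
// [[Rcpp::export(name = ".segment_greedy")]]
IntegerVector segment_greedy(NumericMatrix B, IntegerVector pos,
                             IntegerVector chrom_id, int max_bp, double tau) {
  int n = B.nrow(), G = B.ncol();
  std::vector<int> starts;
  if (n == 0) return IntegerVector(0);
  std::vector<double> cmin(G), cmax(G);
  std::vector<bool> seen(G);
  int bstart = 0;
  starts.push_back(1);
  for (int g = 0; g < G; ++g) {
    double v = B(0, g);
    seen[g] = !NumericVector::is_na(v);
    cmin[g] = cmax[g] = v;
  }
  for (int i = 1; i < n; ++i) {
    bool newblock = chrom_id[i] != chrom_id[bstart] ||
                    (pos[i] + 2 - pos[bstart]) > max_bp;
    if (!newblock) {
      for (int g = 0; g < G && !newblock; ++g) {
        double v = B(i, g);
        if (NumericVector::is_na(v)) continue;
        double lo = seen[g] ? std::min(cmin[g], v) : v;
        double hi = seen[g] ? std::max(cmax[g], v) : v;
        if (hi - lo > tau) newblock = true;
      }
    }
    if (newblock) {
      starts.push_back(i + 1);
      bstart = i;
      for (int g = 0; g < G; ++g) {
        double v = B(i, g);
        seen[g] = !NumericVector::is_na(v);
        cmin[g] = cmax[g] = v;
      }
    } else {
      for (int g = 0; g < G; ++g) {
        double v = B(i, g);
        if (NumericVector::is_na(v)) continue;
        if (!seen[g]) { cmin[g] = cmax[g] = v; seen[g] = true; }
        else {
          if (v < cmin[g]) cmin[g] = v;
          if (v > cmax[g]) cmax[g] = v;
        }
      }
    }
  }
  return wrap(starts);
}
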