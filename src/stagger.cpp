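#include <Rcpp.h>
using namespace Rcpp;

// Sliding-stagger interaction score.
// Residue class codes: 0 other/gap, 1 basic, 2 acidic, 3 hydrophobic.
// At shift s, residue j of seq2 (0-based) aligns at seq1 position j + s;
// pair (i, j) is counted when |i - j - s| <= window of the pair class.
// [[Rcpp::export]]
IntegerVector cpp_stagger_scan(IntegerVector c1, IntegerVector c2,
                               int charge_window, int hydrophobic_window) {
  const int n1 = c1.size(), n2 = c2.size();
  const int wmax = std::max(charge_window, hydrophobic_window);
  IntegerVector out(n1 + n2 - 1);
  for (int s = -(n2 - 1); s <= n1 - 1; ++s) {
    long score = 0;
    for (int j = 0; j < n2; ++j) {
      const int b = c2[j];
      if (b == 0) continue;
      const int centre = j + s; // aligned position on seq1 (0-based)
      for (int d = -wmax; d <= wmax; ++d) {
        const int i = centre + d;
        if (i < 0 || i >= n1) continue;
        const int a = c1[i];
        if (a == 0) continue;
        const int ad = d < 0 ? -d : d;
        if (a == 3 && b == 3) {
          if (ad <= hydrophobic_window) score += 1;
        } else if (a <= 2 && b <= 2) {
          if (ad <= charge_window) score += (a == b) ? -1 : 1;
        }
      }
    }
    out[s + n2 - 1] = (int)score;
  }
  return out;
}
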