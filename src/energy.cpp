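#include <Rcpp.h>
using namespace Rcpp;

// Inter-model nonbonded energy: 12-6 Lennard-Jones (Lorentz-Berthelot
// combination, hard cutoff lj_cut) plus Coulomb with a distance-dependent
// dielectric eps(d) = diel_k * d (so the pair term is kq1q2/(diel_k d^2)),
// hard cutoff coul_cut. Distances are clamped at 0.1 A to keep clashed
// poses finite (they remain hugely positive). Returns c(lj, coulomb).
// [[Rcpp::export]]
NumericVector cpp_pair_energy(NumericMatrix xyz1, NumericMatrix xyz2,
                              NumericVector q1, NumericVector q2,
                              NumericVector sig1, NumericVector sig2,
                              NumericVector eps1, NumericVector eps2,
                              double lj_cut, double coul_cut,
                              double diel_k, double kcoul) {
  const int n1 = xyz1.nrow(), n2 = xyz2.nrow();
  const double lj2 = lj_cut * lj_cut, cc2 = coul_cut * coul_cut;
  double lj = 0.0, coul = 0.0;
  for (int i = 0; i < n1; ++i) {
    const double xi = xyz1(i, 0), yi = xyz1(i, 1), zi = xyz1(i, 2);
    const double qi = q1[i], si = sig1[i], ei = eps1[i];
    for (int j = 0; j < n2; ++j) {
      const double dx = xi - xyz2(j, 0);
      double d2 = dx * dx;
      if (d2 >= cc2) continue;
      const double dy = yi - xyz2(j, 1);
      d2 += dy * dy;
      if (d2 >= cc2) continue;
      const double dz = zi - xyz2(j, 2);
      d2 += dz * dz;
      if (d2 >= cc2) continue;
      if (d2 < 0.01) d2 = 0.01;
      coul += kcoul * qi * q2[j] / (diel_k * d2);
      if (d2 < lj2) {
        const double s = 0.5 * (si + sig2[j]);
        const double e = std::sqrt(ei * eps2[j]);
        const double sr2 = s * s / d2;
        const double sr6 = sr2 * sr2 * sr2;
        lj += 4.0 * e * (sr6 * sr6 - sr6);
      }
    }
  }
  return NumericVector::create(lj, coul);
}
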