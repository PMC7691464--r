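#include <Rcpp.h>
using namespace Rcpp;

// Log-likelihood of every ordered candidate parent pair for every offspring.
//
// par, off: genotype matrices coded 0/1/2 (NA allowed) with loci in columns.
// logT: 27 x m matrix of per-locus log P(g_off | g_par1, g_par2), rows indexed
//       g1 + 3*g2 + 9*go (genotypes 0..2).  Built in R (Mendelian transmission
//       with a genotyping-error mixture), so the error model lives in one place.
//
// Returns an n_off x (n_par * n_par) matrix; column j + n_par*k holds the
// log-likelihood of the pair (parent j+1, parent k+1).  Loci where any of the
// three genotypes is missing contribute nothing (treated as unobserved).
// [[Rcpp::export]]
NumericMatrix pair_logliks_cpp(IntegerMatrix par, IntegerMatrix off,
                               NumericMatrix logT) {
  const int np = par.nrow(), ns = off.nrow(), m = par.ncol();
  if (off.ncol() != m) stop("offspring and parent locus counts differ");
  if (logT.nrow() != 27 || logT.ncol() != m) stop("logT must be 27 x m");
  NumericMatrix out(ns, np * np);

  for (int j = 0; j < np; ++j) {
    for (int k = 0; k < np; ++k) {
      const int col = j + np * k;
      for (int s = 0; s < ns; ++s) {
        double ll = 0.0;
        for (int l = 0; l < m; ++l) {
          const int gj = par(j, l), gk = par(k, l), gs = off(s, l);
          if (gj == NA_INTEGER || gk == NA_INTEGER || gs == NA_INTEGER)
            continue;
          ll += logT(gj + 3 * gk + 9 * gs, l);
        }
        out(s, col) = ll;
      }
    }
  }
  return out;
}

// Count of loci with a strict Mendelian exclusion (zero transmission
// probability under an error-free model) for every ordered parent pair.
// [[Rcpp::export]]
IntegerMatrix pair_mismatch_cpp(IntegerMatrix par, IntegerMatrix off) {
  const int np = par.nrow(), ns = off.nrow(), m = par.ncol();
  IntegerMatrix out(ns, np * np);
  for (int j = 0; j < np; ++j) {
    for (int k = 0; k < np; ++k) {
      const int col = j + np * k;
      for (int s = 0; s < ns; ++s) {
        int bad = 0;
        for (int l = 0; l < m; ++l) {
          const int gj = par(j, l), gk = par(k, l), gs = off(s, l);
          if (gj == NA_INTEGER || gk == NA_INTEGER || gs == NA_INTEGER)
            continue;
          // offspring allele counts impossible given parental dosages:
          // each parent transmits 0 with prob (2-g)/2 and 1 with prob g/2.
          const bool j0 = gj < 2, j1 = gj > 0, k0 = gk < 2, k1 = gk > 0;
          bool ok;
          if (gs == 0)      ok = j0 && k0;
          else if (gs == 2) ok = j1 && k1;
          else              ok = (j0 && k1) || (j1 && k0);
          if (!ok) ++bad;
        }
        out(s, col) = bad;
      }
    }
  }
  return out;
}
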