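#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Minimum, over candidate mechanism tripartitions, of the absolute
// intrinsic difference between the unpartitioned repertoire p and the
// product of part repertoires.
//
// p         : unpartitioned repertoire over the purview Z (length L)
// assign    : nPart x (m + z) matrix of slot assignments (values 0..2);
//             columns 1..m are mechanism nodes, the rest purview nodes.
//             Rows are canonical restricted-growth strings, identity
//             (all zeros) excluded.
// repCache  : list of length 2^m * 2^z; entry a*2^z + b + 1 is the
//             repertoire of mechanism submask a over purview submask b
//             (a numeric vector over the sub-purview's joint states).
// projCache : list of length 2^z; entry b + 1 maps each full-purview
//             state index (0-based) to its substate index on submask b.
// phiCap    : value used for terms with q = 0 < p (R_PosInf = uncapped).
//
// Returns the minimal phi, the 1-based row of the minimizing partition,
// and the 0-based purview state at which the intrinsic difference of that
// partition is maximal (the specified state).  Ties in the minimum keep
// the first partition in enumeration order; ties in the maximum keep the
// first state.
// [[Rcpp::export]]
List cpp_phi_mip(NumericVector p, IntegerMatrix assign, int m, int z,
                 List repCache, List projCache, double phiCap) {
  const int L = p.size();
  const int nPart = assign.nrow();
  const int nRep = repCache.size();
  const int nProj = projCache.size();

  std::vector<NumericVector> reps;
  reps.reserve(nRep);
  for (int i = 0; i < nRep; ++i) reps.push_back(as<NumericVector>(repCache[i]));
  std::vector<IntegerVector> projs;
  projs.reserve(nProj);
  for (int i = 0; i < nProj; ++i) projs.push_back(as<IntegerVector>(projCache[i]));

  double best = R_PosInf;
  int bestRow = -1, bestState = 0;

  for (int rIdx = 0; rIdx < nPart; ++rIdx) {
    int aSub[3] = {0, 0, 0};
    int bSub[3] = {0, 0, 0};
    for (int j = 0; j < m; ++j) aSub[assign(rIdx, j)] |= (1 << j);
    for (int j = 0; j < z; ++j) bSub[assign(rIdx, m + j)] |= (1 << j);

    const double* rep[3];
    const int* proj[3];
    for (int k = 0; k < 3; ++k) {
      rep[k] = REAL(reps[aSub[k] * nProj + bSub[k]]);
      proj[k] = INTEGER(projs[bSub[k]]);
    }

    double phiPart = 0.0;
    int argmax = 0;
    for (int s = 0; s < L; ++s) {
      double ps = p[s];
      if (ps <= 0.0) continue;
      double q = rep[0][proj[0][s]] * rep[1][proj[1][s]] * rep[2][proj[2][s]];
      double term;
      if (q <= 0.0) term = phiCap;
      else term = ps * std::fabs(std::log2(ps / q));
      if (term > phiPart) { phiPart = term; argmax = s; }
      if (phiPart >= best) break;  // cannot improve the running minimum
    }
    if (phiPart < best) {
      best = phiPart;
      bestRow = rIdx;
      bestState = argmax;
      if (best == 0.0) break;  // no partition can do better than 0
    }
  }
  return List::create(_["phi"] = best, _["row"] = bestRow + 1,
                      _["state"] = bestState);
}
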