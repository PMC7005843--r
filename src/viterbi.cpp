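#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Uni-local Viterbi in log2 space. Entry into any match state costs
// -log2(M); exit from any match state is free; flanking residues are
// scored by the null model and contribute 0 log-odds. Emission log-odds
// for residues outside the 20-letter alphabet are 0 (index -1).
//
// lom, loi: M x 20 log2-odds emission matrices (match, insert).
// ltr: M x 7 log2 transition matrix, columns MM MI MD IM II DM DD;
//      row i (0-based) holds node i+1's transitions toward node i+2.
// seq: 0-based alphabet indices, -1 for unknown residues.
// [[Rcpp::export(name = ".viterbiBitsC")]]
double viterbiBitsC(NumericMatrix lom, NumericMatrix loi,
                    NumericMatrix ltr, IntegerVector seq) {
  const int M = lom.nrow();
  const int L = seq.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  const double entry = -std::log2((double)M);

  std::vector<double> prevM(M, NEG), prevI(M, NEG), prevD(M, NEG);
  std::vector<double> curM(M), curI(M), curD(M);
  double best = NEG;

  for (int j = 0; j < L; ++j) {
    int a = seq[j];
    for (int i = 0; i < M; ++i) {
      double em = (a >= 0) ? lom(i, a) : 0.0;
      double sc = entry;  // fresh local entry into match state i
      if (i > 0) {
        double v = prevM[i - 1] + ltr(i - 1, 0);
        if (v > sc) sc = v;
        v = prevI[i - 1] + ltr(i - 1, 3);
        if (v > sc) sc = v;
        v = prevD[i - 1] + ltr(i - 1, 5);
        if (v > sc) sc = v;
      }
      curM[i] = em + sc;
      if (curM[i] > best) best = curM[i];

      double ei = (a >= 0) ? loi(i, a) : 0.0;
      double si = prevM[i] + ltr(i, 1);
      double v2 = prevI[i] + ltr(i, 4);
      if (v2 > si) si = v2;
      curI[i] = ei + si;
    }
    curD[0] = NEG;  // delete states exist for nodes 2..M
    for (int i = 1; i < M; ++i) {
      double sd = curM[i - 1] + ltr(i - 1, 2);
      double v = curD[i - 1] + ltr(i - 1, 6);
      if (v > sd) sd = v;
      curD[i] = sd;
    }
    prevM.swap(curM);
    prevI.swap(curI);
    prevD.swap(curD);
  }
  return best;
}
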