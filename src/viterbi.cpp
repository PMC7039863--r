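#include <Rcpp.h>
using namespace Rcpp;

// Local (Smith-Waterman-style) Viterbi over a Plan7-style profile.
//
// matchLom: L x 20 matrix of log2-odds match emissions.
// Transition vectors are log2 probabilities for moves from position j to
// j+1 (length L-1): mm, mi, md, im, ii, dm, dd.  Insert emissions score 0
// (background).  Entry into any match state and exit from any match state
// are free; an alignment consumes a contiguous query substring and must
// start and end in a match state.  Query residues are 1-based indices into
// the emission columns; 0 denotes the ambiguity residue X and scores 0.
static double viterbi_one(const NumericMatrix& matchLom,
                          const NumericVector& mm, const NumericVector& mi,
                          const NumericVector& md, const NumericVector& im,
                          const NumericVector& ii, const NumericVector& dm,
                          const NumericVector& dd, const IntegerVector& q) {
  const int L = matchLom.nrow();
  const int n = q.size();
  const double NEG = -1e300;
  if (n == 0 || L == 0) return NA_REAL;

  std::vector<double> VMprev(L, NEG), VIprev(L, NEG), VM(L), VI(L), VD(L), VDprev(L, NEG);
  double best = NEG;

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < L; ++j) {
      const int a = q[i];
      const double em = (a == 0) ? 0.0 : matchLom(j, a - 1);
      double m = 0.0;  // fresh local start at M_j
      if (j > 0) {
        if (VMprev[j - 1] + mm[j - 1] > m) m = VMprev[j - 1] + mm[j - 1];
        if (VIprev[j - 1] + im[j - 1] > m) m = VIprev[j - 1] + im[j - 1];
        if (VDprev[j - 1] + dm[j - 1] > m) m = VDprev[j - 1] + dm[j - 1];
      }
      VM[j] = em + m;
      if (VM[j] > best) best = VM[j];
      // insert I_j exists for j < L-1 (between match j+1 and j+2 in 1-based)
      if (j < L - 1) {
        double vi = NEG;
        if (VMprev[j] > NEG / 2) vi = VMprev[j] + mi[j];
        if (VIprev[j] > NEG / 2 && VIprev[j] + ii[j] > vi) vi = VIprev[j] + ii[j];
        VI[j] = vi;
      } else {
        VI[j] = NEG;
      }
    }
    // deletes consume no query residue; filled after VM of this row
    for (int j = 0; j < L; ++j) {
      double vd = NEG;
      if (j > 0) {
        if (VM[j - 1] > NEG / 2) vd = VM[j - 1] + md[j - 1];
        if (VD[j - 1] > NEG / 2 && VD[j - 1] + dd[j - 1] > vd)
          vd = VD[j - 1] + dd[j - 1];
      }
      VD[j] = vd;
    }
    VMprev = VM;
    VIprev = VI;
    VDprev = VD;
  }
  return best;
}

// [[Rcpp::export(name = ".viterbiScore")]]
double viterbiScore(NumericMatrix matchLom, List trans, IntegerVector query) {
  return viterbi_one(matchLom, trans["mm"], trans["mi"], trans["md"],
                     trans["im"], trans["ii"], trans["dm"], trans["dd"], query);
}

// [[Rcpp::export(name = ".viterbiScoreBatch")]]
NumericVector viterbiScoreBatch(NumericMatrix matchLom, List trans, List queries) {
  const int nq = queries.size();
  NumericVector out(nq);
  NumericVector mm = trans["mm"], mi = trans["mi"], md = trans["md"],
                im = trans["im"], ii = trans["ii"], dm = trans["dm"],
                dd = trans["dd"];
  for (int k = 0; k < nq; ++k) {
    IntegerVector q = queries[k];
    out[k] = viterbi_one(matchLom, mm, mi, md, im, ii, dm, dd, q);
  }
  return out;
}
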