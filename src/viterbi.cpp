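#include <Rcpp.h>
using namespace Rcpp;

// Local Viterbi over a match/insert/delete profile model.
//
// emis_lod: nmatch x nresidue matrix of match-state emission log2-odds
//   (log2(p/background)); the residue column indexed by seq[i]. Insert states
//   emit at background (log-odds 0).
// Transitions (log2 probabilities): tmm/tmd [j -> j+1], length M-1;
//   tmi/tii [at j], length M; tim [I_j -> M_j+1], length M-1;
//   tdm/tdd [j -> j+1], length M-1.
// Entry into any match state and exit from any match state are free (plain
// local alignment semantics); the reported score is the best local path
// containing at least one match state, floored at 0.
// Returns 0-based half-open envelope on sequence and model.
// [[Rcpp::export]]
List profile_viterbi_cpp(IntegerVector seq, NumericMatrix emis_lod,
                         NumericVector tmm, NumericVector tmi,
                         NumericVector tmd, NumericVector tim,
                         NumericVector tii, NumericVector tdm,
                         NumericVector tdd) {
  const int L = seq.size(), M = emis_lod.nrow();
  const double NEG = -1e30;
  NumericMatrix VM(L + 1, M + 1), VI(L + 1, M + 1), VD(L + 1, M + 1);
  IntegerMatrix PM(L + 1, M + 1), PI(L + 1, M + 1), PD(L + 1, M + 1);
  std::fill(VM.begin(), VM.end(), NEG);
  std::fill(VI.begin(), VI.end(), NEG);
  std::fill(VD.begin(), VD.end(), NEG);
  double best = 0.0; int bi = -1, bj = -1;
  for (int i = 1; i <= L; ++i) {
    for (int j = 1; j <= M; ++j) {
      // match: emit seq[i-1] at state j
      double e = emis_lod(j - 1, seq[i - 1]);
      double sc = 0.0; int ptr = 0; // 0 = fresh local start
      if (j > 1) {
        double v = VM(i - 1, j - 1) + tmm[j - 2];
        if (v > sc) { sc = v; ptr = 1; }
        v = VI(i - 1, j - 1) + tim[j - 2];
        if (v > sc) { sc = v; ptr = 2; }
        v = VD(i - 1, j - 1) + tdm[j - 2];
        if (v > sc) { sc = v; ptr = 3; }
      }
      VM(i, j) = e + sc; PM(i, j) = ptr;
      if (VM(i, j) > best) { best = VM(i, j); bi = i; bj = j; }
      // insert after state j (emits at background, log-odds 0)
      double vi = VM(i - 1, j) + tmi[j - 1]; int pi = 1;
      double v2 = VI(i - 1, j) + tii[j - 1];
      if (v2 > vi) { vi = v2; pi = 2; }
      VI(i, j) = vi; PI(i, j) = pi;
      // delete state j (no emission)
      if (j > 1) {
        double vd = VM(i, j - 1) + tmd[j - 2]; int pd = 1;
        double v3 = VD(i, j - 1) + tdd[j - 2];
        if (v3 > vd) { vd = v3; pd = 2; }
        VD(i, j) = vd; PD(i, j) = pd;
      }
    }
  }
  if (bi < 0) {
    return List::create(_["bits"] = 0.0, _["seq_start"] = 0,
                        _["seq_end"] = 0, _["hmm_start"] = 0,
                        _["hmm_end"] = 0);
  }
  // traceback from best match cell to the fresh-start match cell
  int i = bi, j = bj, state = 0; // 0 = M, 1 = I, 2 = D
  int si = bi, sj = bj;
  for (;;) {
    if (state == 0) {
      si = i; sj = j;
      int p = PM(i, j);
      if (p == 0) break;
      if (p == 1) { state = 0; } else if (p == 2) { state = 1; }
      else { state = 2; }
      --i; --j; // predecessor of M(i,j) sits at (i-1, j-1)
    } else if (state == 1) {
      int p = PI(i, j);
      state = (p == 1) ? 0 : 1;
      --i;
    } else {
      int p = PD(i, j);
      state = (p == 1) ? 0 : 2;
      --j;
    }
  }
  return List::create(_["bits"] = best,
                      _["seq_start"] = si - 1, _["seq_end"] = bi,
                      _["hmm_start"] = sj - 1, _["hmm_end"] = bj);
}
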