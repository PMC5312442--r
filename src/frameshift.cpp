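#include <Rcpp.h>
using namespace Rcpp;

// Local protein-to-DNA alignment with frameshift transitions.
//
// prot: 0-based indices into scorem rows; dna: 0=A,1=C,2=G,3=T,4=N.
// codon_aa: length-125 lookup, codon index (25*n1 + 5*n2 + n3) -> aa row in
//   scorem ('*' for stops, 'X' for N-containing codons).
// Costs are positive: gap_open/gap_extend for codon-level affine gaps,
// fs_pen per frameshift event, stop_pen for an emitted stop codon (replaces
// the substitution score for matches, added to the gap cost for insertions).
//
// States: H = last op consumed protein and/or emitted a codon (match or
// frameshift), P = gap consuming protein only, Q = gap emitting unmatched
// dna codons. Local paths must start and end on a match.
// [[Rcpp::export]]
List frameshift_align_cpp(IntegerVector prot, IntegerVector dna,
                          NumericMatrix scorem, IntegerVector codon_aa,
                          int stop_idx, double gap_open, double gap_extend,
                          double fs_pen, double stop_pen) {
  const int n = prot.size(), m = dna.size();
  const double NEG = -1e30;
  NumericMatrix H(n + 1, m + 1), P(n + 1, m + 1), Q(n + 1, m + 1);
  IntegerMatrix HOp(n + 1, m + 1), HPrev(n + 1, m + 1);
  IntegerMatrix PPrev(n + 1, m + 1), QPrev(n + 1, m + 1);
  std::fill(H.begin(), H.end(), NEG);
  std::fill(P.begin(), P.end(), NEG);
  std::fill(Q.begin(), Q.end(), NEG);
  double best = NEG; int bi = -1, bj = -1;
  // op codes: 1 match, 2 FSI1, 3 FSI2, 4 FSD1, 5 FSD2
  // prev codes: 0 fresh start, 1 H, 2 P, 3 Q
  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      if (i == 0 && j == 0) continue;
      double h = NEG; int hop = 0, hprev = 0;
      if (i >= 1 && j >= 3) {
        int ci = 25 * dna[j - 3] + 5 * dna[j - 2] + dna[j - 1];
        int aa = codon_aa[ci];
        double s = (aa == stop_idx) ? -stop_pen : scorem(prot[i - 1], aa);
        double base = 0.0; int bp = 0;
        if (H(i - 1, j - 3) > base) { base = H(i - 1, j - 3); bp = 1; }
        if (P(i - 1, j - 3) > base) { base = P(i - 1, j - 3); bp = 2; }
        if (Q(i - 1, j - 3) > base) { base = Q(i - 1, j - 3); bp = 3; }
        h = base + s; hop = 1; hprev = bp;
      }
      for (int k = 1; k <= 2; ++k) { // FSI: excise k inserted nt, no emission
        if (j >= k) {
          double base = std::max(H(i, j - k),
                                 std::max(P(i, j - k), Q(i, j - k)));
          double v = base - fs_pen;
          if (v > h) {
            h = v; hop = 1 + k;
            hprev = (base == H(i, j - k)) ? 1 : (base == P(i, j - k) ? 2 : 3);
          }
        }
      }
      for (int k = 1; k <= 2; ++k) { // FSD: residue with 3-k codon nt lost
        if (i >= 1 && j >= k) {
          double base = std::max(H(i - 1, j - k),
                                 std::max(P(i - 1, j - k), Q(i - 1, j - k)));
          double v = base - fs_pen;
          if (v > h) {
            h = v; hop = 3 + k;
            hprev = (base == H(i - 1, j - k)) ? 1
                    : (base == P(i - 1, j - k) ? 2 : 3);
          }
        }
      }
      H(i, j) = h; HOp(i, j) = hop; HPrev(i, j) = hprev;
      if (hop == 1 && h > best) { best = h; bi = i; bj = j; }
      if (i >= 1) { // P: protein residue unmatched by any dna
        double open = std::max(H(i - 1, j), Q(i - 1, j)) - gap_open - gap_extend;
        double ext = P(i - 1, j) - gap_extend;
        if (open >= ext) {
          P(i, j) = open;
          PPrev(i, j) = (H(i - 1, j) >= Q(i - 1, j)) ? 1 : 3;
        } else { P(i, j) = ext; PPrev(i, j) = 2; }
      }
      if (j >= 3) { // Q: emitted dna codon unmatched by protein
        int ci = 25 * dna[j - 3] + 5 * dna[j - 2] + dna[j - 1];
        double extra = (codon_aa[ci] == stop_idx) ? stop_pen : 0.0;
        double open = std::max(H(i, j - 3), P(i, j - 3)) - gap_open - gap_extend;
        double ext = Q(i, j - 3) - gap_extend;
        if (open >= ext) {
          Q(i, j) = open - extra;
          QPrev(i, j) = (H(i, j - 3) >= P(i, j - 3)) ? 1 : 2;
        } else { Q(i, j) = ext - extra; QPrev(i, j) = 3; }
      }
    }
  }
  if (bi < 0 || best <= 0) {
    return List::create(_["score"] = 0.0, _["found"] = false);
  }
  // traceback
  std::vector<int> codon_starts;            // 0-based dna starts of emitted codons
  std::vector<int> fs_pos, fs_size;         // frameshift events
  int i = bi, j = bj, state = 1;            // 1 H, 2 P, 3 Q
  int pi_end = bi, pj_end = bj, pi_start = bi, pj_start = bj;
  for (;;) {
    if (state == 1) {
      int op = HOp(i, j), prev = HPrev(i, j);
      if (op == 1) {
        codon_starts.push_back(j - 3);
        pi_start = i - 1; pj_start = j - 3;
        i -= 1; j -= 3;
      } else if (op == 2 || op == 3) {
        int k = op - 1;
        fs_pos.push_back(j - k); fs_size.push_back(k); // +k inserted nt
        pj_start = j - k;
        j -= k;
      } else {
        int k = op - 3;
        fs_pos.push_back(j - k); fs_size.push_back(-(3 - k)); // missing nt
        pi_start = i - 1; pj_start = j - k;
        i -= 1; j -= k;
      }
      if (prev == 0) break;
      state = prev;
    } else if (state == 2) {
      int prev = PPrev(i, j);
      pi_start = i - 1;
      i -= 1;
      state = (prev == 2) ? 2 : prev;
    } else {
      int prev = QPrev(i, j);
      codon_starts.push_back(j - 3);
      pj_start = j - 3;
      j -= 3;
      state = (prev == 3) ? 3 : prev;
    }
  }
  std::reverse(codon_starts.begin(), codon_starts.end());
  std::reverse(fs_pos.begin(), fs_pos.end());
  std::reverse(fs_size.begin(), fs_size.end());
  return List::create(_["score"] = best, _["found"] = true,
                      _["codon_starts"] = wrap(codon_starts),
                      _["fs_pos"] = wrap(fs_pos), _["fs_size"] = wrap(fs_size),
                      _["prot_start"] = pi_start, _["prot_end"] = pi_end,
                      _["dna_start"] = pj_start, _["dna_end"] = pj_end);
  }
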