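#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman) over integer-encoded residues.
// a, b: 0-based indices into the rows/cols of `scorem`. Gap of length L costs
// gap_open + L * gap_extend. Traceback tie order: diagonal > up (gap in b) >
// left (gap in a). Returns 0-based half-open envelope coordinates.
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix scorem,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  // H: best ending in match; E: gap in a (left); F: gap in b (up)
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  for (int j = 0; j <= m; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E(i, j) = std::max(H(i, j - 1) - gap_open - gap_extend,
                         E(i, j - 1) - gap_extend);
      F(i, j) = std::max(H(i - 1, j) - gap_open - gap_extend,
                         F(i - 1, j) - gap_extend);
      double diag = H(i - 1, j - 1) + scorem(a[i - 1], b[j - 1]);
      double h = diag;
      if (F(i, j) > h) h = F(i, j);
      if (E(i, j) > h) h = E(i, j);
      if (h < 0) h = 0;
      H(i, j) = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback from (bi, bj) to recover the envelope
  int i = bi, j = bj;
  int state = 0; // 0 = H
  while (i > 0 && j > 0 && H(i, j) > 0) {
    if (state == 0) {
      double diag = H(i - 1, j - 1) + scorem(a[i - 1], b[j - 1]);
      if (H(i, j) == diag) { --i; --j; }
      else if (H(i, j) == F(i, j)) state = 2;
      else state = 1;
    } else if (state == 2) { // F: gap in b, consume a
      if (F(i, j) == H(i - 1, j) - gap_open - gap_extend) { --i; state = 0; }
      else { --i; }
    } else { // E: gap in a, consume b
      if (E(i, j) == H(i, j - 1) - gap_open - gap_extend) { --j; state = 0; }
      else { --j; }
    }
  }
  return List::create(_["score"] = best,
                      _["a_start"] = i, _["a_end"] = bi,
                      _["b_start"] = j, _["b_end"] = bj);
}

// Local alignment scores of one query against many targets (score only).
// [[Rcpp::export]]
NumericVector sw_score_many_cpp(IntegerVector q, List targets,
                                NumericMatrix scorem, double gap_open,
                                double gap_extend) {
  const int nt = targets.size(), n = q.size();
  NumericVector out(nt);
  std::vector<double> H(n + 1), Hd(n + 1), F(n + 1);
  const double NEG = -1e30;
  for (int t = 0; t < nt; ++t) {
    IntegerVector b = targets[t];
    const int m = b.size();
    std::fill(H.begin(), H.end(), 0.0);
    std::fill(F.begin(), F.end(), NEG);
    double best = 0.0;
    for (int j = 1; j <= m; ++j) {
      double e = NEG, diagprev = H[0];
      Hd = H;
      H[0] = 0.0;
      for (int i = 1; i <= n; ++i) {
        e = std::max(H[i - 1] - gap_open - gap_extend, e - gap_extend);
        F[i] = std::max(Hd[i] - gap_open - gap_extend, F[i] - gap_extend);
        double h = Hd[i - 1] + scorem(q[i - 1], b[j - 1]);
        if (F[i] > h) h = F[i];
        if (e > h) h = e;
        if (h < 0) h = 0;
        H[i] = h;
        if (h > best) best = h;
      }
    }
    out[t] = best;
  }
  return out;
}

// Global alignment (Needleman-Wunsch) with affine gaps; returns per-position
// pairing as two gapped index vectors (NA = gap) for MSA merging.
// Traceback tie order: diagonal > up > left.
// [[Rcpp::export]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix scorem,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  H(0, 0) = 0; E(0, 0) = NEG; F(0, 0) = NEG;
  for (int j = 1; j <= m; ++j) {
    E(0, j) = -gap_open - gap_extend * j;
    H(0, j) = E(0, j); F(0, j) = NEG;
  }
  for (int i = 1; i <= n; ++i) {
    F(i, 0) = -gap_open - gap_extend * i;
    H(i, 0) = F(i, 0); E(i, 0) = NEG;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E(i, j) = std::max(H(i, j - 1) - gap_open - gap_extend,
                         E(i, j - 1) - gap_extend);
      F(i, j) = std::max(H(i - 1, j) - gap_open - gap_extend,
                         F(i - 1, j) - gap_extend);
      double diag = H(i - 1, j - 1) + scorem(a[i - 1], b[j - 1]);
      double h = diag;
      if (F(i, j) > h) h = F(i, j);
      if (E(i, j) > h) h = E(i, j);
      H(i, j) = h;
    }
  }
  std::vector<int> ai, bi;
  int i = n, j = m, state = 0;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i > 0 && j > 0 &&
          H(i, j) == H(i - 1, j - 1) + scorem(a[i - 1], b[j - 1])) {
        ai.push_back(i); bi.push_back(j); --i; --j;
      } else if (i > 0 && H(i, j) == F(i, j)) {
        state = 2;
      } else if (j > 0) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 2) {
      bool opened = (j == 0) ? (i == 1 && F(i, 0) == -gap_open - gap_extend)
                             : (F(i, j) == H(i - 1, j) - gap_open - gap_extend);
      ai.push_back(i); bi.push_back(NA_INTEGER); --i;
      if (j == 0) { if (i == 0) break; } else if (opened) state = 0;
    } else {
      bool opened = (i == 0) ? false
                             : (E(i, j) == H(i, j - 1) - gap_open - gap_extend);
      ai.push_back(NA_INTEGER); bi.push_back(j); --j;
      if (i == 0) { if (j == 0) break; } else if (opened) state = 0;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = H(n, m),
                      _["a_idx"] = wrap(ai), _["b_idx"] = wrap(bi));
}
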