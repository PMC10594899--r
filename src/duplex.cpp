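#include <Rcpp.h>
using namespace Rcpp;

// Pair codes shared with the R layer: 0 mismatch, 1 G:U wobble, 2 A:U, 3 G:C.
static inline int pair_code(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 2;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1;
  return 0;
}

// Smith-Waterman local alignment (affine gaps) of the reversed miRNA against
// a UTR window, antiparallel pairing. Substitution scores for positions whose
// ORIGINAL miRNA coordinate lies in [seed_from, seed_to] are multiplied by
// seed_scale; gap penalties are not scaled.
// [[Rcpp::export(name = ".duplex_align_cpp")]]
List duplex_align_cpp(std::string mirna, std::string window,
                      double match, double wobble, double mismatch,
                      double gap_open, double gap_extend,
                      double seed_scale, int seed_from, int seed_to) {
  const int Lm = mirna.size(), Lw = window.size();
  std::string r(mirna.rbegin(), mirna.rend());  // reversed miRNA

  if (Lm == 0 || Lw == 0)
    return List::create(_["score"] = 0.0,
                        _["pairs"] = IntegerMatrix(0, 3));

  const double NEG = -1e9;
  // state matrices, (Lm+1) x (Lw+1); M = aligned pair, X = gap in window,
  // Y = gap in miRNA
  std::vector<std::vector<double>> M(Lm + 1, std::vector<double>(Lw + 1, 0.0));
  std::vector<std::vector<double>> X(Lm + 1, std::vector<double>(Lw + 1, NEG));
  std::vector<std::vector<double>> Y(Lm + 1, std::vector<double>(Lw + 1, NEG));
  // traceback: for M cells, 0 = start (score reset), 1 = from M, 2 = from X,
  // 3 = from Y
  std::vector<std::vector<signed char>> tbM(Lm + 1,
                                            std::vector<signed char>(Lw + 1, 0));
  std::vector<std::vector<signed char>> tbX(Lm + 1,
                                            std::vector<signed char>(Lw + 1, 1));
  std::vector<std::vector<signed char>> tbY(Lm + 1,
                                            std::vector<signed char>(Lw + 1, 1));

  for (int i = 0; i <= Lm; ++i) { M[i][0] = 0.0; }
  for (int j = 0; j <= Lw; ++j) { M[0][j] = 0.0; }

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= Lm; ++i) {
    int orig_pos = Lm - i + 1;  // original 5'->3' miRNA coordinate
    double w = (orig_pos >= seed_from && orig_pos <= seed_to) ? seed_scale : 1.0;
    for (int j = 1; j <= Lw; ++j) {
      int pc = pair_code(r[i - 1], window[j - 1]);
      double s = (pc == 0 ? mismatch : (pc == 1 ? wobble : match)) * w;

      double fromM = M[i - 1][j - 1], fromX = X[i - 1][j - 1],
             fromY = Y[i - 1][j - 1];
      double bestPrev = fromM; signed char tb = 1;
      if (fromX > bestPrev) { bestPrev = fromX; tb = 2; }
      if (fromY > bestPrev) { bestPrev = fromY; tb = 3; }
      double m = bestPrev + s;
      if (m < 0.0) { m = 0.0; tb = 0; }
      M[i][j] = m; tbM[i][j] = tb;

      double xo = M[i - 1][j] - gap_open, xe = X[i - 1][j] - gap_extend;
      if (xo >= xe) { X[i][j] = xo; tbX[i][j] = 1; }
      else          { X[i][j] = xe; tbX[i][j] = 2; }

      double yo = M[i][j - 1] - gap_open, ye = Y[i][j - 1] - gap_extend;
      if (yo >= ye) { Y[i][j] = yo; tbY[i][j] = 1; }
      else          { Y[i][j] = ye; tbY[i][j] = 3; }

      if (M[i][j] > best) { best = M[i][j]; bi = i; bj = j; }
    }
  }

  // traceback aligned pairs from the best M cell
  std::vector<std::array<int, 3>> pairs;
  int i = bi, j = bj, state = 1;  // 1 = M, 2 = X, 3 = Y
  while (i > 0 && j > 0) {
    if (state == 1) {
      if (M[i][j] <= 0.0 && tbM[i][j] == 0) break;
      int pc = pair_code(r[i - 1], window[j - 1]);
      pairs.push_back({Lm - i + 1, j, pc});
      signed char tb = tbM[i][j];
      --i; --j;
      if (tb == 0) break;
      state = tb;
    } else if (state == 2) {
      signed char tb = tbX[i][j];
      --i;
      state = (tb == 1) ? 1 : 2;
    } else {
      signed char tb = tbY[i][j];
      --j;
      state = (tb == 1) ? 1 : 3;
    }
  }

  IntegerMatrix out(pairs.size(), 3);
  for (size_t k = 0; k < pairs.size(); ++k) {
    // reverse so rows run 5'->3' along the window
    const std::array<int, 3> &p = pairs[pairs.size() - 1 - k];
    out(k, 0) = p[0]; out(k, 1) = p[1]; out(k, 2) = p[2];
  }
  colnames(out) = CharacterVector::create("mirna_pos", "window_pos", "code");
  return List::create(_["score"] = best, _["pairs"] = out);
}
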