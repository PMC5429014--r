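// Deterministic dynamic-programming aligners:
//  - global profile-profile alignment (Gotoh affine gaps) over frequency
//    profiles scored against a substitution matrix; used by the progressive
//    codon-aware aligner
//  - local Smith-Waterman score for nucleotide best-hit search
//
// Gap convention: a gap of length L costs open + (L-1) * extend.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// profA, profB: nsym x LA / nsym x LB column frequency profiles (gaps carry
// zero mass); sub: nsym x nsym substitution scores.
// Returns alignment as two integer vectors (1-based source column, 0 = gap).
// [[Rcpp::export(name = ".cpp_profile_align")]]
Rcpp::List cpp_profile_align(const arma::mat &profA, const arma::mat &profB,
                             const arma::mat &sub, double gap_open,
                             double gap_ext) {
  const int LA = profA.n_cols, LB = profB.n_cols;
  const double NEG = -1e30;
  mat S = profA.t() * (sub * profB);  // LA x LB column-pair scores

  // Gotoh: Mm = match end, Ix = gap in B (consume A col), Iy = gap in A
  mat Mm(LA + 1, LB + 1), Ix(LA + 1, LB + 1), Iy(LA + 1, LB + 1);
  // traceback: 0 diag(M), 1 from Ix, 2 from Iy; per matrix
  imat tM(LA + 1, LB + 1, fill::zeros), tX(LA + 1, LB + 1, fill::zeros),
      tY(LA + 1, LB + 1, fill::zeros);
  Mm.fill(NEG); Ix.fill(NEG); Iy.fill(NEG);
  Mm(0, 0) = 0.0;
  for (int i = 1; i <= LA; ++i) {
    Ix(i, 0) = -gap_open - (i - 1) * gap_ext;
    tX(i, 0) = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= LB; ++j) {
    Iy(0, j) = -gap_open - (j - 1) * gap_ext;
    tY(0, j) = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= LA; ++i) {
    for (int j = 1; j <= LB; ++j) {
      // match: priority diag > Ix > Iy on ties
      double s = S(i - 1, j - 1);
      double m0 = Mm(i - 1, j - 1), m1 = Ix(i - 1, j - 1), m2 = Iy(i - 1, j - 1);
      int tb = 0; double best = m0;
      if (m1 > best) { best = m1; tb = 1; }
      if (m2 > best) { best = m2; tb = 2; }
      Mm(i, j) = best + s; tM(i, j) = tb;
      // Ix: consume column i of A against gap
      double x0 = Mm(i - 1, j) - gap_open, x1 = Ix(i - 1, j) - gap_ext,
             x2 = Iy(i - 1, j) - gap_open;
      tb = 0; best = x0;
      if (x1 > best) { best = x1; tb = 1; }
      if (x2 > best) { best = x2; tb = 2; }
      Ix(i, j) = best; tX(i, j) = tb;
      // Iy: consume column j of B against gap
      double y0 = Mm(i, j - 1) - gap_open, y1 = Ix(i, j - 1) - gap_open,
             y2 = Iy(i, j - 1) - gap_ext;
      tb = 0; best = y0;
      if (y1 > best) { best = y1; tb = 1; }
      if (y2 > best) { best = y2; tb = 2; }
      Iy(i, j) = best; tY(i, j) = tb;
    }
  }
  int state = 0;
  double fin = Mm(LA, LB);
  if (Ix(LA, LB) > fin) { fin = Ix(LA, LB); state = 1; }
  if (Iy(LA, LB) > fin) { fin = Iy(LA, LB); state = 2; }

  std::vector<int> ca, cb;
  int i = LA, j = LB;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tM(i, j);
      ca.push_back(i); cb.push_back(j);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tX(i, j);
      ca.push_back(i); cb.push_back(0);
      --i; state = prev;
    } else {
      int prev = tY(i, j);
      ca.push_back(0); cb.push_back(j);
      --j; state = prev;
    }
  }
  std::reverse(ca.begin(), ca.end());
  std::reverse(cb.begin(), cb.end());
  return Rcpp::List::create(Rcpp::Named("score") = fin,
                            Rcpp::Named("a") = ca, Rcpp::Named("b") = cb);
}

// Local alignment score (Smith-Waterman, affine gaps with the same
// open + (L-1)*extend convention). a, b: integer-coded sequences.
// [[Rcpp::export(name = ".cpp_sw_score")]]
double cpp_sw_score(const arma::ivec &a, const arma::ivec &b, double match,
                    double mismatch, double gap_open, double gap_ext) {
  const int n = a.n_elem, m = b.n_elem;
  const double NEG = -1e30;
  std::vector<double> H(m + 1, 0.0), E(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diag = 0.0;       // H[i-1][j-1]
    double F = NEG;          // gap in b along row
    double Hprev = 0.0;      // H[i][0]
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(H[j] - gap_open, E[j] - gap_ext);
      F = std::max(Hprev - gap_open, F - gap_ext);
      double s = (a(i - 1) == b(j - 1)) ? match : mismatch;
      double h = std::max(0.0, std::max(diag + s, std::max(E[j], F)));
      diag = H[j];
      H[j] = h;
      Hprev = h;
      if (h > best) best = h;
    }
  }
  return best;
}
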