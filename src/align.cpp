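#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap pairwise alignment kernels (Gotoh). A gap run of length L costs
// gap_open + L * gap_extend. Local (Smith-Waterman) and end-gap-free global
// ("overlap") variants share the residue-pair scoring setup below.

static const double NEG = -1e18;

struct Scorer {
  int idx[256];
  std::vector<double> mat; // nletters x nletters
  int n;
  double score(unsigned char a, unsigned char b) const {
    int ia = idx[a], ib = idx[b];
    if (ia < 0 || ib < 0) {
      // 'X' is neutral when absent from the matrix; anything else is an error
      if ((ia < 0 && a != 'X') || (ib < 0 && b != 'X'))
        stop("residue letter not covered by the substitution matrix");
      return 0.0;
    }
    return mat[ia * n + ib];
  }
};

static Scorer make_scorer(const NumericMatrix& sub) {
  Scorer sc;
  for (int i = 0; i < 256; ++i) sc.idx[i] = -1;
  CharacterVector rn = rownames(sub);
  sc.n = sub.nrow();
  if (sc.n != sub.ncol()) stop("substitution matrix must be square");
  for (int i = 0; i < sc.n; ++i) {
    std::string s = as<std::string>(rn[i]);
    if (s.size() != 1) stop("substitution matrix letters must be single characters");
    sc.idx[(unsigned char)s[0]] = i;
  }
  sc.mat.resize((size_t)sc.n * sc.n);
  for (int i = 0; i < sc.n; ++i)
    for (int j = 0; j < sc.n; ++j)
      sc.mat[i * sc.n + j] = sub(i, j);
  // validate all letters up front so errors name the offending character
  return sc;
}

static void check_letters(const std::string& s, const Scorer& sc, const char* arg) {
  for (size_t i = 0; i < s.size(); ++i) {
    unsigned char c = s[i];
    if (sc.idx[c] < 0 && c != 'X')
      stop("unknown residue '%s' at position %d of %s",
           std::string(1, (char)c).c_str(), (int)(i + 1), arg);
  }
}

enum Ptr { P_STOP = 0, P_DIAG = 1, P_UP = 2, P_LEFT = 3 };

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  Scorer sc = make_scorer(sub);
  check_letters(a, sc, "a");
  check_letters(b, sc, "b");
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  size_t W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  // ptrM: where the H value feeding M[i][j] came from (0 = fresh start)
  std::vector<unsigned char> ptrM((n + 1) * W, 0), ptrX((n + 1) * W, 0), ptrY((n + 1) * W, 0);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      size_t k = i * W + j, kd = (i - 1) * W + (j - 1), ku = (i - 1) * W + j, kl = i * W + (j - 1);
      // M: a[i] aligned to b[j]
      double h = 0.0; unsigned char p = P_STOP;
      if (M[kd] > h) { h = M[kd]; p = P_DIAG; }
      if (X[kd] > h) { h = X[kd]; p = P_UP; }
      if (Y[kd] > h) { h = Y[kd]; p = P_LEFT; }
      M[k] = sc.score(a[i - 1], b[j - 1]) + h;
      ptrM[k] = p;
      // X: gap in b, consuming a[i]
      double xo = (M[ku] > Y[ku] ? M[ku] : Y[ku]) - gap_open - gap_extend;
      double xe = X[ku] - gap_extend;
      if (xo >= xe) { X[k] = xo; ptrX[k] = (M[ku] >= Y[ku]) ? P_DIAG : P_LEFT; }
      else { X[k] = xe; ptrX[k] = P_UP; }
      // Y: gap in a, consuming b[j]
      double yo = (M[kl] > X[kl] ? M[kl] : X[kl]) - gap_open - gap_extend;
      double ye = Y[kl] - gap_extend;
      if (yo >= ye) { Y[k] = yo; ptrY[k] = (M[kl] >= X[kl]) ? P_DIAG : P_UP; }
      else { Y[k] = ye; ptrY[k] = P_LEFT; }
      if (M[k] > best + 1e-12) { best = M[k]; bi = i; bj = j; }
    }
  }
  int nident = 0, ncols = 0;
  int a_start = 0, a_end = 0, b_start = 0, b_end = 0;
  if (best > 0.0) {
    a_end = bi; b_end = bj;
    int i = bi, j = bj;
    int state = 0; // 0 = M, 1 = X, 2 = Y
    while (i > 0 && j > 0) {
      size_t k = i * W + j;
      if (state == 0) {
        ++ncols;
        if (a[i - 1] == b[j - 1]) ++nident;
        unsigned char p = ptrM[k];
        --i; --j;
        if (p == P_STOP) break;
        state = (p == P_DIAG) ? 0 : (p == P_UP ? 1 : 2);
      } else if (state == 1) {
        ++ncols;
        unsigned char p = ptrX[k];
        --i;
        state = (p == P_DIAG) ? 0 : (p == P_UP ? 1 : 2);
      } else {
        ++ncols;
        unsigned char p = ptrY[k];
        --j;
        state = (p == P_DIAG) ? 0 : (p == P_UP ? 1 : 2);
      }
    }
    a_start = i + 1; b_start = j + 1;
  }
  return List::create(_["score"] = best, _["nident"] = nident, _["ncols"] = ncols,
                      _["a_start"] = a_start, _["a_end"] = a_end,
                      _["b_start"] = b_start, _["b_end"] = b_end);
}

// [[Rcpp::export(name = ".nw_overlap_cpp")]]
List nw_overlap_cpp(std::string a, std::string b, NumericMatrix sub,
                    double gap_open, double gap_extend) {
  Scorer sc = make_scorer(sub);
  check_letters(a, sc, "a");
  check_letters(b, sc, "b");
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  size_t W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  std::vector<unsigned char> ptrM((n + 1) * W, 0), ptrX((n + 1) * W, 0), ptrY((n + 1) * W, 0);
  // leading end gaps are free: treat border H as 0
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      size_t k = i * W + j, kd = (i - 1) * W + (j - 1), ku = (i - 1) * W + j, kl = i * W + (j - 1);
      double hd, hu, hl;
      unsigned char pd;
      if (i - 1 == 0 || j - 1 == 0) { hd = 0.0; pd = P_STOP; }
      else {
        hd = M[kd]; pd = P_DIAG;
        if (X[kd] > hd) { hd = X[kd]; pd = P_UP; }
        if (Y[kd] > hd) { hd = Y[kd]; pd = P_LEFT; }
      }
      M[k] = sc.score(a[i - 1], b[j - 1]) + hd;
      ptrM[k] = pd;
      if (i - 1 == 0) { hu = NEG; } else { hu = (M[ku] > Y[ku] ? M[ku] : Y[ku]); }
      double xo = hu - gap_open - gap_extend;
      double xe = X[ku] - gap_extend;
      if (xo >= xe) { X[k] = xo; ptrX[k] = (i - 1 > 0 && M[ku] >= Y[ku]) ? P_DIAG : P_LEFT; }
      else { X[k] = xe; ptrX[k] = P_UP; }
      if (j - 1 == 0) { hl = NEG; } else { hl = (M[kl] > X[kl] ? M[kl] : X[kl]); }
      double yo = hl - gap_open - gap_extend;
      double ye = Y[kl] - gap_extend;
      if (yo >= ye) { Y[k] = yo; ptrY[k] = (j - 1 > 0 && M[kl] >= X[kl]) ? P_DIAG : P_UP; }
      else { Y[k] = ye; ptrY[k] = P_LEFT; }
    }
  }
  // trailing end gaps free: best over last row and last column, M state only
  // (an optimal end-gap-free alignment ends on an aligned column)
  double best = NEG;
  int bi = n, bj = m;
  for (int j = 1; j <= m; ++j)
    if (M[n * W + j] > best + 1e-12) { best = M[n * W + j]; bi = n; bj = j; }
  for (int i = 1; i <= n; ++i)
    if (M[i * W + m] > best + 1e-12) { best = M[i * W + m]; bi = i; bj = m; }
  int nident = 0, ncols = 0;
  int i = bi, j = bj, state = 0;
  bool any = best > NEG / 2;
  if (any) {
    while (i > 0 && j > 0) {
      size_t k = i * W + j;
      if (state == 0) {
        ++ncols;
        if (a[i - 1] == b[j - 1]) ++nident;
        unsigned char p = ptrM[k];
        --i; --j;
        if (p == P_STOP) break;
        state = (p == P_DIAG) ? 0 : (p == P_UP ? 1 : 2);
      } else if (state == 1) {
        ++ncols; unsigned char p = ptrX[k]; --i;
        state = (p == P_DIAG) ? 0 : (p == P_UP ? 1 : 2);
      } else {
        ++ncols; unsigned char p = ptrY[k]; --j;
        state = (p == P_DIAG) ? 0 : (p == P_UP ? 1 : 2);
      }
    }
  }
  return List::create(_["score"] = any ? best : 0.0, _["nident"] = nident,
                      _["ncols"] = ncols);
}
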