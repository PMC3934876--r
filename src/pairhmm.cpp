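#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// log(exp(a) + exp(b)) without underflow
static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  if (a < b) std::swap(a, b);
  return a + std::log1p(std::exp(b - a));
}

static inline double lg(double p) {
  return p > 0.0 ? std::log(p) : NEG_INF;
}

// Five-state pair HMM posterior decoding.
//
// States: 1 = match, 2/3 = short insert in x/y, 4/5 = long insert in x/y.
// x, y are 1-based integer residue codes. init is the 5-vector of start
// probabilities, trans the 5x5 row-stochastic transition table, memit the
// KxK joint match emission table, iemit the length-K single-residue
// emission table shared by the four insert states.
//
// A path starts in any state (weight init[s]) and ends in any state
// (weight 1); the forward-backward product over the match state divided by
// the total path mass gives P(x_i ~ y_j). All arithmetic is in log space.
// [[Rcpp::export]]
NumericMatrix hmm_posterior_cpp(IntegerVector x, IntegerVector y,
                                NumericVector init, NumericMatrix trans,
                                NumericMatrix memit, NumericVector iemit) {
  const int lx = x.size(), ly = y.size();
  const int nx = lx + 1, ny = ly + 1;

  double li[5], lt[5][5];
  for (int s = 0; s < 5; ++s) {
    li[s] = lg(init[s]);
    for (int t = 0; t < 5; ++t) lt[s][t] = lg(trans(s, t));
  }

  // f[s][i*ny + j]: log mass of paths emitting x[1..i], y[1..j], ending in s
  std::vector<std::vector<double>> f(5, std::vector<double>((size_t)nx * ny, NEG_INF));
  std::vector<std::vector<double>> b(5, std::vector<double>((size_t)nx * ny, NEG_INF));

  // log emissions per position
  std::vector<double> lex(lx), ley(ly);
  for (int i = 0; i < lx; ++i) lex[i] = lg(iemit[x[i] - 1]);
  for (int j = 0; j < ly; ++j) ley[j] = lg(iemit[y[j] - 1]);

  // forward
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      const size_t c = (size_t)i * ny + j;
      if (i > 0 && j > 0) {
        const size_t d = (size_t)(i - 1) * ny + (j - 1);
        double em = lg(memit(x[i - 1] - 1, y[j - 1] - 1));
        double acc = (i == 1 && j == 1) ? li[0] : NEG_INF;
        if (!(i == 1 && j == 1))
          for (int s = 0; s < 5; ++s) acc = lse2(acc, f[s][d] + lt[s][0]);
        f[0][c] = acc + em;
      }
      if (i > 0) {  // x-insert states 2 (short) and 4 (long)
        const size_t u = (size_t)(i - 1) * ny + j;
        for (int s : {1, 3}) {
          double acc = (i == 1 && j == 0) ? li[s] : NEG_INF;
          if (!(i == 1 && j == 0))
            for (int t = 0; t < 5; ++t) acc = lse2(acc, f[t][u] + lt[t][s]);
          f[s][c] = acc + lex[i - 1];
        }
      }
      if (j > 0) {  // y-insert states 3 (short) and 5 (long)
        const size_t l = (size_t)i * ny + (j - 1);
        for (int s : {2, 4}) {
          double acc = (i == 0 && j == 1) ? li[s] : NEG_INF;
          if (!(i == 0 && j == 1))
            for (int t = 0; t < 5; ++t) acc = lse2(acc, f[t][l] + lt[t][s]);
          f[s][c] = acc + ley[j - 1];
        }
      }
    }
  }

  // backward: b[s][i,j] = log mass of emitting x[i+1..lx], y[j+1..ly]
  // given current state s (emission of (i,j) already accounted in f)
  for (int i = lx; i >= 0; --i) {
    for (int j = ly; j >= 0; --j) {
      const size_t c = (size_t)i * ny + j;
      for (int s = 0; s < 5; ++s) {
        double acc = (i == lx && j == ly) ? 0.0 : NEG_INF;
        if (i < lx && j < ly) {
          const size_t d = (size_t)(i + 1) * ny + (j + 1);
          acc = lse2(acc, lt[s][0] + lg(memit(x[i] - 1, y[j] - 1)) + b[0][d]);
        }
        if (i < lx) {
          const size_t u = (size_t)(i + 1) * ny + j;
          acc = lse2(acc, lt[s][1] + lex[i] + b[1][u]);
          acc = lse2(acc, lt[s][3] + lex[i] + b[3][u]);
        }
        if (j < ly) {
          const size_t l = (size_t)i * ny + (j + 1);
          acc = lse2(acc, lt[s][2] + ley[j] + b[2][l]);
          acc = lse2(acc, lt[s][4] + ley[j] + b[4][l]);
        }
        b[s][c] = acc;
      }
    }
  }

  double ltot = NEG_INF;
  const size_t end = (size_t)lx * ny + ly;
  for (int s = 0; s < 5; ++s) ltot = lse2(ltot, f[s][end]);

  NumericMatrix post(nx, ny);
  for (int i = 1; i < nx; ++i)
    for (int j = 1; j < ny; ++j) {
      const size_t c = (size_t)i * ny + j;
      double lp = f[0][c] + b[0][c] - ltot;
      post(i, j) = (lp == NEG_INF) ? 0.0 : std::exp(lp);
    }
  return post;
}

// Partition-function posterior with affine gaps.
//
// Z accumulates Boltzmann weights exp(beta * score) over all global
// alignments; a gap run of length L scores gap_open + (L-1)*gap_ext,
// terminal gaps included. Posterior(i,j) =
//   Zf(i-1,j-1) * exp(beta*s(x_i,y_j)) * Zr(i,j) / Ztot,
// where Zf/Zr sum over prefix/suffix alignments ending/starting in any
// state. Log space throughout.
// [[Rcpp::export]]
NumericMatrix pf_posterior_cpp(IntegerVector x, IntegerVector y,
                               NumericMatrix score, double beta,
                               double gap_open, double gap_ext) {
  const int lx = x.size(), ly = y.size();
  const int nx = lx + 1, ny = ly + 1;
  const double go = beta * gap_open, ge = beta * gap_ext;

  // three-state log partition function over prefixes:
  // M ends in match, X ends in gap-in-y (x consumed), Y ends in gap-in-x
  auto run = [&](bool reverse) {
    std::vector<double> M((size_t)nx * ny, NEG_INF),
        X((size_t)nx * ny, NEG_INF), Y((size_t)nx * ny, NEG_INF);
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) {
        const size_t c = (size_t)i * ny + j;
        if (i == 0 && j == 0) { M[c] = 0.0; continue; }  // empty prefix, state-free start
        if (i > 0 && j > 0) {
          int xi = reverse ? x[lx - i] : x[i - 1];
          int yj = reverse ? y[ly - j] : y[j - 1];
          const size_t d = (size_t)(i - 1) * ny + (j - 1);
          double s = beta * score(xi - 1, yj - 1);
          M[c] = lse2(lse2(M[d], X[d]), Y[d]) + s;
        }
        if (i > 0) {
          const size_t u = (size_t)(i - 1) * ny + j;
          X[c] = lse2(lse2(M[u], Y[u]) + go, X[u] + ge);
        }
        if (j > 0) {
          const size_t l = (size_t)i * ny + (j - 1);
          Y[c] = lse2(lse2(M[l], X[l]) + go, Y[l] + ge);
        }
      }
    }
    std::vector<std::vector<double>> out;
    out.push_back(std::move(M)); out.push_back(std::move(X)); out.push_back(std::move(Y));
    return out;
  };

  auto F = run(false);  // forward over prefixes
  auto R = run(true);   // same DP on reversed sequences = suffix ensembles

  const size_t end = (size_t)lx * ny + ly;
  double ltot = lse2(lse2(F[0][end], F[1][end]), F[2][end]);

  NumericMatrix post(nx, ny);
  for (int i = 1; i < nx; ++i) {
    for (int j = 1; j < ny; ++j) {
      // prefix x[1..i-1],y[1..j-1] in any state; match (i,j); suffix
      // x[i+1..],y[j+1..] = reverse-DP cell (lx-i, ly-j) in any state
      const size_t p = (size_t)(i - 1) * ny + (j - 1);
      const size_t s = (size_t)(lx - i) * ny + (ly - j);
      double lpre = lse2(lse2(F[0][p], F[1][p]), F[2][p]);
      double lsuf = lse2(lse2(R[0][s], R[1][s]), R[2][s]);
      double lp = lpre + beta * score(x[i - 1] - 1, y[j - 1] - 1) + lsuf - ltot;
      post(i, j) = (lp == NEG_INF) ? 0.0 : std::exp(lp);
    }
  }
  return post;
}
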