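#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Weighted consistency relaxation of one sparse posterior matrix:
//
//   P'_xy = [ (w_x + w_y) P_xy + sum_z w_z (P_xz x P_zy) ] / W,
//   W = (w_x + w_y) + sum_z w_z
//
// evaluated on the support of P_xy only (no fill-in): a product cell with
// no matching element in P_xy is discarded. Sparse operands arrive as
// parallel vectors (row offsets are 0-based starts into col/val; column
// indices are 1-based residue positions). Returns the new value vector
// aligned with P_xy's element order; support and ordering are unchanged.
//
// zx_* hold the c concatenated P_xz operands, zy_* the c P_zy operands,
// in matching order (rows of P_xz = residues of x, rows of P_zy = residues
// of z).
// [[Rcpp::export]]
NumericVector relax_pair_cpp(int n_rows, int n_cols,
                             IntegerVector xy_sizes, IntegerVector xy_offsets,
                             IntegerVector xy_col, NumericVector xy_val,
                             double wxy, NumericVector wz,
                             List zx_sizes, List zx_offsets, List zx_col, List zx_val,
                             List zy_sizes, List zy_offsets, List zy_col, List zy_val) {
  const int nz = wz.size();
  NumericVector out(xy_val.size());
  double W = wxy;
  for (int z = 0; z < nz; ++z) W += wz[z];

  // hoist operand vectors out of the row loop
  std::vector<IntegerVector> XS(nz), XO(nz), XC(nz), YS(nz), YO(nz), YC(nz);
  std::vector<NumericVector> XV(nz), YV(nz);
  for (int z = 0; z < nz; ++z) {
    XS[z] = zx_sizes[z]; XO[z] = zx_offsets[z]; XC[z] = zx_col[z]; XV[z] = zx_val[z];
    YS[z] = zy_sizes[z]; YO[z] = zy_offsets[z]; YC[z] = zy_col[z]; YV[z] = zy_val[z];
  }

  std::vector<double> buf(n_cols + 1, 0.0);

  for (int i = 0; i < n_rows; ++i) {
    const int si = xy_sizes[i];
    if (si == 0) continue;
    const int oi = xy_offsets[i];

    for (int e = 0; e < si; ++e) buf[xy_col[oi + e]] = wxy * xy_val[oi + e];

    for (int z = 0; z < nz; ++z) {
      const double w = wz[z];
      const int sxi = XS[z][i], oxi = XO[z][i];
      for (int e = 0; e < sxi; ++e) {
        const int k = XC[z][oxi + e] - 1;   // residue of z, row of P_zy
        const double v = w * XV[z][oxi + e];
        const int syk = YS[z][k], oyk = YO[z][k];
        for (int g = 0; g < syk; ++g) buf[YC[z][oyk + g]] += v * YV[z][oyk + g];
      }
    }

    for (int e = 0; e < si; ++e) {
      const int c = xy_col[oi + e];
      out[oi + e] = buf[c] / W;
    }
    // reset the buffer, including product spill outside the support
    for (int e = 0; e < si; ++e) buf[xy_col[oi + e]] = 0.0;
    for (int z = 0; z < nz; ++z) {
      const int sxi = XS[z][i], oxi = XO[z][i];
      for (int e = 0; e < sxi; ++e) {
        const int k = XC[z][oxi + e] - 1;
        const int syk = YS[z][k], oyk = YO[z][k];
        for (int g = 0; g < syk; ++g) buf[YC[z][oyk + g]] = 0.0;
      }
    }
  }
  return out;
}
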