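// Per-pixel 3x3 Mueller matrix polar decomposition (MMPD) and MMT
// anisotropy parameter. Mirrors the single-matrix R implementation
// (mmpd(), mmt_t()) exactly; exists because parameter maps and cohort
// simulations apply it to ~10^4-10^6 pixels.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// mflat: n_pixels x 9, row-major element order (m11, m12, ..., m33),
// rows already normalized by m11. Returns n_pixels x 7:
// D, Delta, 1-Delta, delta_ret, t_minus, t_plus, valid(0/1).
// [[Rcpp::export]]
arma::mat decompose_pixels_cpp(const arma::mat& mflat, double eig_tol) {
  const uword n = mflat.n_rows;
  mat out(n, 7);
  out.fill(datum::nan);
  out.col(6).zeros();

  mat M(3, 3), MDinv(3, 3), MDR(3, 3);
  vec lam(3);
  mat vecs(3, 3);

  for (uword p = 0; p < n; ++p) {
    const rowvec r = mflat.row(p);
    if (!r.is_finite()) continue;

    // row-major unpack
    M(0, 0) = r(0); M(0, 1) = r(1); M(0, 2) = r(2);
    M(1, 0) = r(3); M(1, 1) = r(4); M(1, 2) = r(5);
    M(2, 0) = r(6); M(2, 1) = r(7); M(2, 2) = r(8);

    const double d1 = M(0, 1), d2 = M(0, 2);
    const double D2 = d1 * d1 + d2 * d2;
    const double D = std::sqrt(D2);
    if (D >= 1.0 - 1e-9) continue;  // singular diattenuator: mask

    mat Mp;
    if (D2 == 0.0) {
      Mp = M;
    } else {
      const double a = std::sqrt(1.0 - D2);
      const double b = 1.0 - a;
      mat MD = {{1.0, d1, d2},
                {d1, a + b * d1 * d1 / D2, b * d1 * d2 / D2},
                {d2, b * d1 * d2 / D2, a + b * d2 * d2 / D2}};
      if (!inv(MDinv, MD)) continue;
      Mp = M * MDinv;
    }
    MDR = Mp * Mp.t();
    if (!eig_sym(lam, vecs, MDR)) continue;

    // drop the intensity-channel eigenvalue (eigenvector along s0)
    uword unit_idx = index_max(abs(vecs.row(0).t()));
    double big = -datum::inf, small_ = datum::inf;
    for (uword k = 0; k < 3; ++k) {
      if (k == unit_idx) continue;
      if (lam(k) > big) big = lam(k);
      if (lam(k) < small_) small_ = lam(k);
    }
    if (small_ < -eig_tol) continue;  // unphysical: mask
    big = std::max(big, 0.0);
    small_ = std::max(small_, 0.0);

    const double delta_dep = std::min(1.0, std::sqrt(big));
    const double delta_ret =
        (big > 0.0) ? std::acos(std::sqrt(std::min(1.0, small_ / big))) : 0.0;

    const double dm = M(1, 1) - M(2, 2);
    const double om = M(1, 2) - M(2, 1);
    const double op = M(1, 2) + M(2, 1);

    out(p, 0) = std::min(1.0, D);
    out(p, 1) = delta_dep;
    out(p, 2) = 1.0 - delta_dep;
    out(p, 3) = delta_ret;
    out(p, 4) = std::sqrt(dm * dm + om * om) / 2.0;
    out(p, 5) = std::sqrt(dm * dm + op * op) / 2.0;
    out(p, 6) = 1.0;
  }
  return out;
}
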