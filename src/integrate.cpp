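#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Fixed-step classical RK4 integration of the canonical-microcircuit
// flow from the zero state.
//
//   v' = g
//   g' = kappa % (W f(v) + c u) - 2 kappa % g - kappa^2 % v
//
// with f(v) = tanh(fg * v). `u` must be sampled at half-step
// resolution: u[2*j], u[2*j+1], u[2*j+2] are the drive at the start,
// mid-point and end of global sub-step j. Returns the voltage of every
// population at the `n_out` output samples (substeps internal steps
// per output sample). Throws if any state magnitude exceeds `bound`.
// [[Rcpp::export(name = ".cmc_integrate_cpp")]]
arma::mat cmc_integrate_cpp(const arma::mat& W,
                            const arma::vec& cvec,
                            const arma::vec& kappa,
                            const double fg,
                            const arma::vec& u,
                            const double h,
                            const int n_out,
                            const int substeps,
                            const double bound) {
  const arma::uword np = kappa.n_elem;
  arma::vec v(np, arma::fill::zeros), g(np, arma::fill::zeros);
  arma::mat out(n_out, np, arma::fill::zeros);
  const arma::vec k2v = kappa % kappa;

  // one flow evaluation: dv = g, dg = kappa % drive - 2 kappa % g - kappa^2 % v
  auto flow = [&](const arma::vec& vv, const arma::vec& gg, const double uu,
                  arma::vec& dv, arma::vec& dg) {
    dv = gg;
    dg = kappa % (W * arma::tanh(fg * vv) + cvec * uu)
         - 2.0 * (kappa % gg) - k2v % vv;
  };

  arma::vec dv1(np), dg1(np), dv2(np), dg2(np), dv3(np), dg3(np),
      dv4(np), dg4(np), vt(np), gt(np);

  long ustep = 0;  // global sub-step index
  for (int i = 1; i < n_out; ++i) {
    for (int s = 0; s < substeps; ++s, ++ustep) {
      const double u0 = u[2 * ustep], um = u[2 * ustep + 1],
                   u1 = u[2 * ustep + 2];
      flow(v, g, u0, dv1, dg1);
      vt = v + 0.5 * h * dv1; gt = g + 0.5 * h * dg1;
      flow(vt, gt, um, dv2, dg2);
      vt = v + 0.5 * h * dv2; gt = g + 0.5 * h * dg2;
      flow(vt, gt, um, dv3, dg3);
      vt = v + h * dv3; gt = g + h * dg3;
      flow(vt, gt, u1, dv4, dg4);
      v += h / 6.0 * (dv1 + 2.0 * dv2 + 2.0 * dv3 + dv4);
      g += h / 6.0 * (dg1 + 2.0 * dg2 + 2.0 * dg3 + dg4);
    }
    if (!v.is_finite() || !g.is_finite() ||
        std::max(arma::abs(v).max(), arma::abs(g).max()) > bound) {
      stop("numerical blow-up during integration (|state| exceeded bound)");
    }
    out.row(i) = v.t();
  }
  return out;
}
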