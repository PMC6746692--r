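#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// One semi-implicit additive-operator-splitting step for
//   du/dt = div(G(u) grad u) - f0,  G(u) = g / |grad u|_eps1,
// with the exact-penalty update damped by Btilde = diag(tau * alpha * btilde):
//   utilde = u - tau (I + Btilde)^{-1} f0
//   u_new  = 1/2 sum_l (I - 2 tau (I + Btilde)^{-1} A_l)^{-1} utilde,
// A_l the 1-D diffusion operator along rows (l=1) / columns (l=2) with
// half-point diffusivities and zero-flux (Neumann) ends. Each 1-D system is
// tridiagonal and solved by the Thomas algorithm.
//
// Gradients of u use central differences in the interior and one-sided
// differences on the border, matching the R-level convention.

static void thomas(const std::vector<double>& lo, const std::vector<double>& di,
                   const std::vector<double>& up, const std::vector<double>& rhs,
                   std::vector<double>& x, std::vector<double>& cp,
                   std::vector<double>& dp) {
  const int n = (int)di.size();
  cp[0] = up[0] / di[0];
  dp[0] = rhs[0] / di[0];
  for (int i = 1; i < n; ++i) {
    const double m = di[i] - lo[i] * cp[i - 1];
    cp[i] = up[i] / m;
    dp[i] = (rhs[i] - lo[i] * dp[i - 1]) / m;
  }
  x[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = dp[i] - cp[i] * x[i + 1];
}

// [[Rcpp::export]]
NumericMatrix aos_step_cpp(NumericMatrix u, NumericMatrix g,
                           NumericMatrix f0, NumericMatrix btilde,
                           double tau, double alpha, double eps1) {
  const int nr = u.nrow(), nc = u.ncol();
  NumericMatrix G(nr, nc), out(nr, nc);

  // diffusivity G = g / sqrt(|grad u|^2 + eps1^2)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double gr = 0.0, gc = 0.0;
      if (nr > 1) {
        if (i == 0)            gr = u(1, j) - u(0, j);
        else if (i == nr - 1)  gr = u(nr - 1, j) - u(nr - 2, j);
        else                   gr = 0.5 * (u(i + 1, j) - u(i - 1, j));
      }
      if (nc > 1) {
        if (j == 0)            gc = u(i, 1) - u(i, 0);
        else if (j == nc - 1)  gc = u(i, nc - 1) - u(i, nc - 2);
        else                   gc = 0.5 * (u(i, j + 1) - u(i, j - 1));
      }
      G(i, j) = g(i, j) / std::sqrt(gr * gr + gc * gc + eps1 * eps1);
    }
  }

  const int nmax = std::max(nr, nc);
  std::vector<double> lo(nmax), di(nmax), up(nmax), rhs(nmax), x(nmax),
      cp(nmax), dp(nmax);

  // utilde, reused as rhs for both directions
  NumericMatrix ut(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      const double den = 1.0 + tau * alpha * btilde(i, j);
      ut(i, j) = u(i, j) - tau * f0(i, j) / den;
    }

  // direction 1: along rows (varying row index, fixed column)
  for (int j = 0; j < nc; ++j) {
    lo.assign(nr, 0.0); di.assign(nr, 0.0); up.assign(nr, 0.0);
    for (int i = 0; i < nr; ++i) {
      const double den = 1.0 + tau * alpha * btilde(i, j);
      const double c = 2.0 * tau / den;
      const double Gm = (i > 0)      ? 0.5 * (G(i, j) + G(i - 1, j)) : 0.0;
      const double Gp = (i < nr - 1) ? 0.5 * (G(i, j) + G(i + 1, j)) : 0.0;
      lo[i] = -c * Gm;
      up[i] = -c * Gp;
      di[i] = 1.0 + c * (Gm + Gp);
      rhs[i] = ut(i, j);
    }
    lo.resize(nr); di.resize(nr); up.resize(nr); rhs.resize(nr);
    thomas(lo, di, up, rhs, x, cp, dp);
    for (int i = 0; i < nr; ++i) out(i, j) = 0.5 * x[i];
  }

  // direction 2: along columns
  for (int i = 0; i < nr; ++i) {
    lo.assign(nc, 0.0); di.assign(nc, 0.0); up.assign(nc, 0.0);
    rhs.resize(nc);
    for (int j = 0; j < nc; ++j) {
      const double den = 1.0 + tau * alpha * btilde(i, j);
      const double c = 2.0 * tau / den;
      const double Gm = (j > 0)      ? 0.5 * (G(i, j) + G(i, j - 1)) : 0.0;
      const double Gp = (j < nc - 1) ? 0.5 * (G(i, j) + G(i, j + 1)) : 0.0;
      lo[j] = -c * Gm;
      up[j] = -c * Gp;
      di[j] = 1.0 + c * (Gm + Gp);
      rhs[j] = ut(i, j);
    }
    thomas(lo, di, up, rhs, x, cp, dp);
    for (int j = 0; j < nc; ++j) out(i, j) += 0.5 * x[j];
  }

  if (!is_true(all(is_finite(out))))
    stop("non-finite values in AOS update; consider a smaller time step tau");
  return out;
}
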