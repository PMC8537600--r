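// Scattering amplitudes of a concentric two-layer (core + shell) sphere,
// Aden-Kerker extension of the Mie series, real refractive indices.
//
// Notation follows Bohren & Huffman: Riccati-Bessel psi_n(z) = z j_n(z),
// chi_n(z) = -z y_n(z), xi_n = psi_n - i chi_n.  psi is generated by
// Miller's downward recurrence (normalised to psi_0 = sin z), chi by the
// stable upward recurrence, and the core only ever enters through the
// logarithmic derivative D_n = psi'_n / psi_n, so no under/overflow from
// the core argument can reach the coefficients.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cplx;

static int n_terms(double x) {
  // Wiscombe truncation for the outer size parameter
  int n = (int)std::ceil(x + 4.05 * std::cbrt(x) + 2.0);
  return n < 3 ? 3 : n;
}

// psi_0..psi_nmax and chi_0..chi_nmax at real z > 0
static void riccati(double z, int nmax, std::vector<double> &psi,
                    std::vector<double> &chi) {
  psi.assign(nmax + 1, 0.0);
  chi.assign(nmax + 1, 0.0);
  // downward ratio recurrence r_n = psi_n / psi_{n-1}
  int nstart = nmax + 16 + (int)std::ceil(std::sqrt((double)nmax + z));
  double r = z / (2.0 * nstart + 1.0);
  std::vector<double> rat(nmax + 1, 0.0);
  for (int n = nstart; n >= 1; --n) {
    double denom = (2.0 * n + 1.0) / z - r;
    r = 1.0 / denom;
    if (n <= nmax) rat[n] = r;
  }
  psi[0] = std::sin(z);
  for (int n = 1; n <= nmax; ++n) psi[n] = rat[n] * psi[n - 1];
  chi[0] = std::cos(z);
  if (nmax >= 1) chi[1] = std::cos(z) / z + std::sin(z);
  for (int n = 1; n < nmax; ++n)
    chi[n + 1] = (2.0 * n + 1.0) / z * chi[n] - chi[n - 1];
}

// logarithmic derivative D_n(z) = psi'_n(z)/psi_n(z), downward recurrence
static void log_deriv(double z, int nmax, std::vector<double> &d) {
  d.assign(nmax + 1, 0.0);
  int nstart = nmax + 16 + (int)std::ceil(std::sqrt((double)nmax + z));
  double dn = 0.0; // D_nstart
  for (int n = nstart; n >= 1; --n) {
    double v = n / z;
    dn = v - 1.0 / (dn + v); // now D_{n-1}
    if (n - 1 >= 1 && n - 1 <= nmax) d[n - 1] = dn;
  }
}

// expansion coefficients a_n, b_n (n = 1..nmax) for the coated sphere
static void coated_ab(double x_core, double x_shell, double m1, double m2,
                      int nmax, std::vector<cplx> &a, std::vector<cplx> &b) {
  const double y = x_shell;
  const double z1 = m1 * x_core, z2 = m2 * x_core, y2 = m2 * y;
  const bool uniform = (m1 == m2) || (x_core <= 0.0);

  std::vector<double> psiy, chiy, psiy2, chiy2, psiz2, chiz2, d1;
  riccati(y, nmax, psiy, chiy);
  riccati(y2, nmax, psiy2, chiy2);
  if (!uniform) {
    riccati(z2, nmax, psiz2, chiz2);
    log_deriv(z1, nmax, d1);
  }

  a.assign(nmax + 1, cplx(0.0, 0.0));
  b.assign(nmax + 1, cplx(0.0, 0.0));

  for (int n = 1; n <= nmax; ++n) {
    double An = 0.0, Bn = 0.0;
    if (!uniform) {
      // derivatives from recurrence f'_n = f_{n-1} - (n/z) f_n
      double dpz2 = psiz2[n - 1] - n / z2 * psiz2[n];
      double dcz2 = chiz2[n - 1] - n / z2 * chiz2[n];
      double D = d1[n];
      double an_num = m2 * psiz2[n] * D - m1 * dpz2;
      double an_den = m2 * chiz2[n] * D - m1 * dcz2;
      double bn_num = m2 * dpz2 - m1 * D * psiz2[n];
      double bn_den = m2 * dcz2 - m1 * D * chiz2[n];
      if (an_den != 0.0 && std::isfinite(an_num / an_den)) An = an_num / an_den;
      if (bn_den != 0.0 && std::isfinite(bn_num / bn_den)) Bn = bn_num / bn_den;
    }
    double dpy = psiy[n - 1] - n / y * psiy[n];
    double dcy = chiy[n - 1] - n / y * chiy[n];
    double dpy2 = psiy2[n - 1] - n / y2 * psiy2[n];
    double dcy2 = chiy2[n - 1] - n / y2 * chiy2[n];
    cplx xin(psiy[n], -chiy[n]);
    cplx dxin(dpy, -dcy);

    double u = dpy2 - An * dcy2;        // psi' - A chi'  at m2 y
    double v = psiy2[n] - An * chiy2[n]; // psi  - A chi   at m2 y
    cplx a_num = psiy[n] * u - m2 * dpy * v;
    cplx a_den = xin * u - m2 * dxin * v;
    a[n] = a_num / a_den;

    double ub = dpy2 - Bn * dcy2;
    double vb = psiy2[n] - Bn * chiy2[n];
    cplx b_num = m2 * psiy[n] * ub - dpy * vb;
    cplx b_den = m2 * xin * ub - dxin * vb;
    b[n] = b_num / b_den;
  }
}

// S1, S2 at the given cos(theta) values
static void amplitudes(const std::vector<cplx> &a, const std::vector<cplx> &b,
                       int nmax, const NumericVector &mu,
                       std::vector<cplx> &S1, std::vector<cplx> &S2) {
  const int nt = mu.size();
  S1.assign(nt, cplx(0.0, 0.0));
  S2.assign(nt, cplx(0.0, 0.0));
  for (int k = 0; k < nt; ++k) {
    double u = mu[k];
    double pi_nm1 = 0.0, pi_n = 1.0; // pi_0, pi_1
    cplx s1(0.0, 0.0), s2(0.0, 0.0);
    for (int n = 1; n <= nmax; ++n) {
      double tau_n = n * u * pi_n - (n + 1.0) * pi_nm1;
      double f = (2.0 * n + 1.0) / (n * (n + 1.0));
      s1 += f * (a[n] * pi_n + b[n] * tau_n);
      s2 += f * (a[n] * tau_n + b[n] * pi_n);
      double pi_np1 = ((2.0 * n + 1.0) * u * pi_n - (n + 1.0) * pi_nm1) / n;
      pi_nm1 = pi_n;
      pi_n = pi_np1;
    }
    S1[k] = s1;
    S2[k] = s2;
  }
}

//' @noRd
// [[Rcpp::export]]
List mie_coated_cpp(double x_core, double x_shell, double m_core,
                    double m_shell, NumericVector mu) {
  if (!(x_shell > 0.0) || x_shell > 300.0)
    stop("size parameter x = %f outside (0, 300]: series not evaluated",
         x_shell);
  int nmax = n_terms(x_shell);
  std::vector<cplx> a, b, S1, S2;
  coated_ab(x_core, x_shell, m_core, m_shell, nmax, a, b);
  amplitudes(a, b, nmax, mu, S1, S2);
  ComplexVector s1(mu.size()), s2(mu.size());
  for (int k = 0; k < mu.size(); ++k) {
    s1[k].r = S1[k].real();
    s1[k].i = S1[k].imag();
    s2[k].r = S2[k].real();
    s2[k].i = S2[k].imag();
  }
  return List::create(_["S1"] = s1, _["S2"] = s2, _["n_terms"] = nmax);
}

// Batch of unpolarised intensity profiles S11 = (|S1|^2 + |S2|^2)/2.
// params columns: x_core, x_shell, m_core, m_shell; one profile per row.
//' @noRd
// [[Rcpp::export]]
NumericMatrix mie_s11_batch_cpp(NumericMatrix params, NumericVector mu,
                                bool normalize) {
  const int np = params.nrow(), nt = mu.size();
  NumericMatrix out(np, nt);
  std::vector<cplx> a, b, S1, S2;
  for (int i = 0; i < np; ++i) {
    double xc = params(i, 0), xs = params(i, 1);
    double m1 = params(i, 2), m2 = params(i, 3);
    if (!(xs > 0.0) || xs > 300.0)
      stop("row %d: size parameter x = %f outside (0, 300]", i + 1, xs);
    int nmax = n_terms(xs);
    coated_ab(xc, xs, m1, m2, nmax, a, b);
    amplitudes(a, b, nmax, mu, S1, S2);
    double mx = 0.0;
    for (int k = 0; k < nt; ++k) {
      double s11 = 0.5 * (std::norm(S1[k]) + std::norm(S2[k]));
      out(i, k) = s11;
      if (s11 > mx) mx = s11;
    }
    if (normalize && mx > 0.0)
      for (int k = 0; k < nt; ++k) out(i, k) /= mx;
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
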