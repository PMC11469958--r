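// Transient (pulse-labelled) PMF of the two-state telegraph model.
//
// The labelled-count master equation, written for the promoter-state resolved
// generating functions G_i(z, t) = sum_n P(state i, n labelled) z^n, is a
// first-order PDE that reduces along its characteristics
//   z(s) = 1 + (z - 1) exp(-k_d (t - s))
// to the 2x2 linear, time-varying ODE
//   dV/ds = A(s) V,   A(s) = [ -k_on            k_off
//                               k_on   k_syn (z(s)-1) - k_off ],
// with initial condition V(0) = (1 - occ, occ), occ = k_on/(k_on + k_off)
// (promoter at stationarity, zero labelled molecules).  G(z, t) = V_0 + V_1.
// The PMF is recovered from PGF values on the unit circle by FFT.
//
// The ODE is propagated with a 4th-order Magnus integrator (two-point Gauss
// quadrature plus the leading commutator), each step applied through the
// closed-form exponential of a complex 2x2 matrix.  |V| <= 1 on the unit
// disk, so the computation is well conditioned in double precision; step
// doubling with Richardson extrapolation controls the local error.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
typedef std::complex<double> cplx;

struct M2 { cplx a, b, c, d; };  // [[a, b], [c, d]]

static inline M2 add(const M2 &x, const M2 &y) {
  return M2{x.a + y.a, x.b + y.b, x.c + y.c, x.d + y.d};
}
static inline M2 scale(const M2 &x, cplx s) {
  return M2{x.a * s, x.b * s, x.c * s, x.d * s};
}
static inline M2 mmul(const M2 &x, const M2 &y) {
  return M2{x.a * y.a + x.b * y.c, x.a * y.b + x.b * y.d,
            x.c * y.a + x.d * y.c, x.c * y.b + x.d * y.d};
}

// v <- exp(A) v, closed form for 2x2 complex A
static inline void expm_apply(const M2 &A, cplx &v0, cplx &v1) {
  const cplx mu = 0.5 * (A.a + A.d);
  const cplx del2 = 0.25 * (A.a - A.d) * (A.a - A.d) + A.b * A.c;
  const cplx del = std::sqrt(del2);
  cplx ch, shc;  // cosh(del), sinh(del)/del
  if (std::abs(del) < 1e-5) {
    ch = 1.0 + del2 / 2.0 + del2 * del2 / 24.0;
    shc = 1.0 + del2 / 6.0 + del2 * del2 / 120.0;
  } else {
    ch = std::cosh(del);
    shc = std::sinh(del) / del;
  }
  const cplx e = std::exp(mu);
  const cplx t00 = e * (ch + shc * (A.a - mu));
  const cplx t11 = e * (ch + shc * (A.d - mu));
  const cplx t01 = e * shc * A.b;
  const cplx t10 = e * shc * A.c;
  const cplx w0 = t00 * v0 + t01 * v1;
  const cplx w1 = t10 * v0 + t11 * v1;
  v0 = w0;
  v1 = w1;
}

struct NodeODE {
  double kon, koff, ksyn, kd, t;
  cplx w;  // z - 1 for this node
  // A(s)
  inline M2 A(double s) const {
    const cplx f = ksyn * w * std::exp(-kd * (t - s));
    return M2{cplx(-kon, 0.0), cplx(koff, 0.0), cplx(kon, 0.0), f - koff};
  }
  // single Magnus-4 step of size h starting at s, applied to (v0, v1)
  inline void magnus4(double s, double h, cplx &v0, cplx &v1) const {
    const double c1 = 0.5 - 0.2886751345948129;  // 1/2 - sqrt(3)/6
    const double c2 = 0.5 + 0.2886751345948129;
    const M2 A1 = A(s + c1 * h);
    const M2 A2 = A(s + c2 * h);
    M2 omega = scale(add(A1, A2), cplx(0.5 * h, 0.0));
    const M2 comm = add(mmul(A2, A1), scale(mmul(A1, A2), cplx(-1.0, 0.0)));
    omega = add(omega, scale(comm, cplx(0.14433756729740646 * h * h, 0.0)));
    expm_apply(omega, v0, v1);
  }
};

// integrate one node from s0 to t with adaptive step doubling
static bool integrate_node(const NodeODE &ode, double s0, double tol,
                           long max_steps, cplx &v0, cplx &v1) {
  double s = s0;
  const double T = ode.t;
  if (T <= s0) return true;
  double h = (T - s0) / 16.0;
  long steps = 0;
  while (s < T) {
    if (++steps > max_steps) return false;
    if (s + h > T) h = T - s;
    // full step
    cplx b0 = v0, b1 = v1;
    ode.magnus4(s, h, b0, b1);
    // two half steps
    cplx s0c = v0, s1c = v1;
    ode.magnus4(s, 0.5 * h, s0c, s1c);
    ode.magnus4(s + 0.5 * h, 0.5 * h, s0c, s1c);
    const double err =
        std::max(std::abs(s0c - b0), std::abs(s1c - b1)) / 15.0;
    if (err < tol || h <= 1e-12 * T) {
      // accept with Richardson extrapolation (order 5)
      v0 = s0c + (s0c - b0) / 15.0;
      v1 = s1c + (s1c - b1) / 15.0;
      s += h;
      const double grow = (err > 0.0)
          ? std::min(4.0, std::max(0.3, 0.9 * std::pow(tol / err, 0.2)))
          : 4.0;
      h *= grow;
    } else {
      h *= std::max(0.2, 0.9 * std::pow(tol / err, 0.2));
    }
  }
  return true;
}

//' @noRd
// [[Rcpp::export(name = ".pgf_pmf_engine")]]
arma::vec pgf_pmf_engine(double kon, double koff, double ksyn, double kd,
                         double t, int m, double tol, double window_log) {
  const double occ = kon / (kon + koff);
  // labelled molecules created more than window_log/kd before t are below
  // double-precision relevance; start the integration there
  const double s0 = (kd > 0.0) ? std::max(0.0, t - window_log / kd) : 0.0;

  arma::cx_vec G(m);
  G(0) = cplx(1.0, 0.0);  // z = 1: stationarity is an exact fixed point
  const double two_pi = 6.283185307179586476925286766559;
  const long max_steps = 2000000L;
  for (int j = 1; j <= m / 2; ++j) {
    const double th = two_pi * j / m;
    const cplx z(std::cos(th), std::sin(th));
    NodeODE ode{kon, koff, ksyn, kd, t, z - 1.0};
    cplx v0(1.0 - occ, 0.0), v1(occ, 0.0);
    if (!integrate_node(ode, s0, tol, max_steps, v0, v1))
      Rcpp::stop("PGF characteristic integration failed to converge");
    G(j) = v0 + v1;
    if (j < m - j) G(m - j) = std::conj(G(j));
  }
  arma::cx_vec P = arma::fft(G);
  return arma::real(P) / static_cast<double>(m);
}

//' @noRd
// [[Rcpp::export(name = ".negll_tab")]]
double negll_tab(const arma::vec &tab, const arma::vec &pmf, double floor_p) {
  // tab[k+1] = number of cells with count k; pmf must cover max count
  double ll = 0.0;
  for (arma::uword k = 0; k < tab.n_elem; ++k) {
    if (tab(k) > 0.0) {
      double p = pmf(k);
      if (p < floor_p) p = floor_p;
      ll += tab(k) * std::log(p);
    }
  }
  return -ll;
}
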