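// Vidberg-Serene continued-fraction Pade coefficients, computed with
// compensated double-double (~106-bit) complex arithmetic: the g-function
// recursion is notoriously ill-conditioned and plain doubles lose node
// reproduction already around 20-30 points. Final evaluation is done in
// ordinary double precision.

#include <Rcpp.h>
#include <cmath>
#include <complex>
#include <vector>

using namespace Rcpp;

// ---- double-double real arithmetic -----------------------------------------
struct dd {
  double hi, lo;
  dd(double h = 0.0, double l = 0.0) : hi(h), lo(l) {}
};

static inline dd two_sum(double a, double b) {
  double s = a + b;
  double bb = s - a;
  double err = (a - (s - bb)) + (b - bb);
  return dd(s, err);
}

static inline dd two_prod(double a, double b) {
  double p = a * b;
  double err = std::fma(a, b, -p);
  return dd(p, err);
}

static inline dd add(const dd& a, const dd& b) {
  dd s = two_sum(a.hi, b.hi);
  double lo = s.lo + a.lo + b.lo;
  dd r = two_sum(s.hi, lo);
  return r;
}

static inline dd sub(const dd& a, const dd& b) { return add(a, dd(-b.hi, -b.lo)); }

static inline dd mul(const dd& a, const dd& b) {
  dd p = two_prod(a.hi, b.hi);
  p.lo += a.hi * b.lo + a.lo * b.hi;
  return two_sum(p.hi, p.lo);
}

static inline dd div_dd(const dd& a, const dd& b) {
  double q1 = a.hi / b.hi;
  dd r = sub(a, mul(dd(q1), b));
  double q2 = r.hi / b.hi;
  r = sub(r, mul(dd(q2), b));
  double q3 = r.hi / b.hi;
  dd q = two_sum(q1, q2);
  return add(q, dd(q3));
}

// ---- double-double complex --------------------------------------------------
struct ddc {
  dd re, im;
  ddc() {}
  ddc(dd r, dd i) : re(r), im(i) {}
  ddc(double r, double i) : re(r), im(i) {}
};

static inline ddc add(const ddc& a, const ddc& b) {
  return ddc(add(a.re, b.re), add(a.im, b.im));
}
static inline ddc sub(const ddc& a, const ddc& b) {
  return ddc(sub(a.re, b.re), sub(a.im, b.im));
}
static inline ddc mul(const ddc& a, const ddc& b) {
  return ddc(sub(mul(a.re, b.re), mul(a.im, b.im)),
             add(mul(a.re, b.im), mul(a.im, b.re)));
}
static inline ddc div_c(const ddc& a, const ddc& b) {
  dd den = add(mul(b.re, b.re), mul(b.im, b.im));
  ddc num = mul(a, ddc(b.re, dd(-b.im.hi, -b.im.lo)));
  return ddc(div_dd(num.re, den), div_dd(num.im, den));
}
static inline double abs2(const ddc& a) {
  return a.re.hi * a.re.hi + a.im.hi * a.im.hi;
}

// ---- Vidberg-Serene recursion ----------------------------------------------
// g_1(z_i) = u_i;  a_p = g_p(z_p);
// g_{p+1}(z_i) = (g_p(z_p) - g_p(z_i)) / ((z_i - z_p) g_p(z_i))
// Returns the continued-fraction coefficients a_i (doubles) plus a status:
// 0 ok, p > 0 means the recursion hit g_p(z_p) ~ 0 / non-finite at stage p.
// [[Rcpp::export(name = "cpp_pade_fit")]]
List cpp_pade_fit(ComplexVector z, ComplexVector u, bool extended = true) {
  int n = z.size();
  std::vector<ddc> g(n), zn(n);
  for (int i = 0; i < n; ++i) {
    g[i] = ddc(u[i].r, u[i].i);
    zn[i] = ddc(z[i].r, z[i].i);
  }
  ComplexVector a(n);
  int status = 0;
  if (!extended) {
    // plain double-precision variant (kept for the precision regression test)
    std::vector<std::complex<double>> gd(n), zd(n);
    for (int i = 0; i < n; ++i) {
      gd[i] = std::complex<double>(u[i].r, u[i].i);
      zd[i] = std::complex<double>(z[i].r, z[i].i);
    }
    for (int p = 0; p < n; ++p) {
      a[p].r = gd[p].real();
      a[p].i = gd[p].imag();
      if (p == n - 1) break;
      std::complex<double> gp = gd[p];
      if (!std::isfinite(gp.real()) || !std::isfinite(gp.imag())) {
        status = p + 1;
        break;
      }
      for (int i = p + 1; i < n; ++i) {
        std::complex<double> den = (zd[i] - zd[p]) * gd[i];
        if (std::abs(den) == 0.0) { status = p + 1; break; }
        gd[i] = (gp - gd[i]) / den;
      }
      if (status) break;
    }
    return List::create(_["coeffs"] = a, _["status"] = status);
  }
  for (int p = 0; p < n; ++p) {
    a[p].r = g[p].re.hi + g[p].re.lo;
    a[p].i = g[p].im.hi + g[p].im.lo;
    if (p == n - 1) break;
    ddc gp = g[p];
    if (!std::isfinite(gp.re.hi) || !std::isfinite(gp.im.hi)) {
      status = p + 1;
      break;
    }
    for (int i = p + 1; i < n; ++i) {
      ddc den = mul(sub(zn[i], zn[p]), g[i]);
      if (abs2(den) == 0.0 || !std::isfinite(abs2(den))) {
        status = p + 1;
        break;
      }
      g[i] = div_c(sub(gp, g[i]), den);
    }
    if (status) break;
  }
  return List::create(_["coeffs"] = a, _["status"] = status);
}

// bottom-up evaluation of the continued fraction
//   f(z) = a_1 / (1 + a_2 (z - z_1) / (1 + a_3 (z - z_2) / (1 + ...)))
// [[Rcpp::export(name = "cpp_pade_eval")]]
ComplexVector cpp_pade_eval(ComplexVector a, ComplexVector z_nodes,
                            ComplexVector z_eval) {
  int n = a.size(), m = z_eval.size();
  ComplexVector out(m);
  for (int k = 0; k < m; ++k) {
    std::complex<double> z(z_eval[k].r, z_eval[k].i);
    std::complex<double> w(1.0, 0.0);
    for (int i = n - 1; i >= 1; --i) {
      std::complex<double> zi(z_nodes[i - 1].r, z_nodes[i - 1].i);
      std::complex<double> ai(a[i].r, a[i].i);
      w = 1.0 + ai * (z - zi) / w;  // division by 0 -> Inf, handled below
    }
    std::complex<double> f = std::complex<double>(a[0].r, a[0].i) / w;
    if (!std::isfinite(f.real()) || !std::isfinite(f.imag())) {
      out[k].r = NA_REAL;
      out[k].i = NA_REAL;
    } else {
      out[k].r = f.real();
      out[k].i = f.imag();
    }
  }
  return out;
}

// Batched fit+evaluate for the self-energy continuation: one Pade model per
// (p, q) element (p <= q), data sigma_even + i sigma_odd over the frequency
// nodes, evaluated at targets[q] + i eta and targets[p] + i eta. Returns the
// matrix E with E[p, q] = Re Sigma_pq(targets[q] + i eta) (and transpose
// position from the row target), plus a fit-failure count.
// [[Rcpp::export(name = "cpp_continue_sigma")]]
List cpp_continue_sigma(NumericVector omega, NumericVector even,
                        NumericVector odd, int nmo, NumericVector targets,
                        double eta, bool static_offdiag = false) {
  int nw = omega.size();
  NumericMatrix out(nmo, nmo);
  int nfail = 0;
  std::vector<ddc> zn(nw), g(nw);
  std::vector<std::complex<double>> zd(nw), a(nw);
  for (int i = 0; i < nw; ++i) {
    zn[i] = ddc(0.0, omega[i]);
    zd[i] = std::complex<double>(0.0, omega[i]);
  }
  size_t nn = (size_t)nmo * nmo;
  for (int p = 0; p < nmo; ++p)
    for (int q = p; q < nmo; ++q) {
      double mx = 0.0;
      for (int i = 0; i < nw; ++i) {
        double er = even[(size_t)i * nn + (size_t)q * nmo + p];
        double oi = odd[(size_t)i * nn + (size_t)q * nmo + p];
        g[i] = ddc(er, oi);
        double m = std::abs(er) + std::abs(oi);
        if (m > mx) mx = m;
      }
      if (mx < 1e-14) continue;
      // Vidberg-Serene recursion in double-double
      bool ok = true;
      int neff = nw;
      for (int s = 0; s < neff; ++s) {
        a[s] = std::complex<double>(g[s].re.hi + g[s].re.lo,
                                    g[s].im.hi + g[s].im.lo);
        if (s == neff - 1) break;
        ddc gp = g[s];
        if (!std::isfinite(gp.re.hi) || !std::isfinite(gp.im.hi)) {
          ok = false;
          break;
        }
        for (int i = s + 1; i < neff; ++i) {
          ddc den = mul(sub(zn[i], zn[s]), g[i]);
          double d2 = abs2(den);
          if (d2 == 0.0 || !std::isfinite(d2)) { ok = false; break; }
          g[i] = div_c(sub(gp, g[i]), den);
        }
        if (!ok) break;
      }
      if (!ok) { nfail++; continue; }
      // evaluate at the two element targets (or the static limit for
      // off-diagonal elements in the mode-B construction)
      double tg[2] = { targets[q], targets[p] };
      if (static_offdiag && p != q) { tg[0] = 0.0; tg[1] = 0.0; }
      double vals[2];
      bool evalok = true;
      for (int t = 0; t < 2; ++t) {
        std::complex<double> z(tg[t], eta);
        std::complex<double> w(1.0, 0.0);
        for (int i = neff - 1; i >= 1; --i)
          w = 1.0 + a[i] * (z - zd[i - 1]) / w;
        std::complex<double> f = a[0] / w;
        if (!std::isfinite(f.real())) { evalok = false; break; }
        vals[t] = f.real();
      }
      if (!evalok) { nfail++; continue; }
      out(p, q) = vals[0];
      out(q, p) = vals[1];
    }
  return List::create(_["E"] = out, _["nfail"] = nfail);
}
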