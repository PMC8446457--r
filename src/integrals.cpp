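// Gaussian integral engine (McMurchie-Davidson scheme) for the mean-field
// backend: overlap, kinetic, nuclear attraction, 2-/3-/4-center electron
// repulsion integrals over contracted cartesian Gaussians, and basis-set
// evaluation (values + gradients) on quadrature grids.
//
// AOs are *unnormalized* cartesian primitives x^i y^j z^k exp(-a r^2)
// contracted with the raw coefficients passed in; the R side rescales every
// AO so that S_ii = 1, which fixes the normalization convention once for all
// integral classes consistently.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// ---------------------------------------------------------------------------
// Boys function F_m(x), m = 0..mmax, stable double-precision evaluation.
// Series for small/moderate x with downward recursion, asymptotic for large x.
static void boys(int mmax, double x, double* F) {
  if (x < 1e-14) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (x > 35.0) {
    // asymptotic: F_0 = sqrt(pi/x)/2, upward recursion is stable here
    F[0] = 0.5 * std::sqrt(PI / x);
    double ex = (x > 700.0) ? 0.0 : std::exp(-x);
    for (int m = 1; m <= mmax; ++m)
      F[m] = ((2.0 * m - 1.0) * F[m - 1] - ex) * 0.5 / x;
    return;
  }
  // series for F_mmax: F_m(x) = exp(-x) * sum_k (2m-1)!! (2x)^k / (2m+2k+1)!!
  double ex = std::exp(-x);
  double sum = 1.0 / (2.0 * mmax + 1.0);
  double term = sum;
  for (int k = 1; k < 400; ++k) {
    term *= 2.0 * x / (2.0 * mmax + 2.0 * k + 1.0);
    sum += term;
    if (term < sum * 1e-17) break;
  }
  F[mmax] = ex * sum;
  // downward recursion: F_{m-1} = (2x F_m + exp(-x)) / (2m-1)
  for (int m = mmax; m >= 1; --m)
    F[m - 1] = (2.0 * x * F[m] + ex) / (2.0 * m - 1.0);
}

// ---------------------------------------------------------------------------
// Hermite expansion coefficients E_t^{ij} for one cartesian dimension.
// E is indexed E[(i*(lb+1)+j)*(la+lb+1)+t].
struct Etab {
  int la, lb;
  std::vector<double> v;
  inline double get(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(size_t)(i * (lb + 1) + j) * (la + lb + 1) + t];
  }
};

static void build_E(Etab& E, int la, int lb, double a, double b,
                    double A, double B) {
  E.la = la; E.lb = lb;
  E.v.assign((size_t)(la + 1) * (lb + 1) * (la + lb + 1), 0.0);
  double p = a + b, mu = a * b / p;
  double AB = A - B;
  double PA = -b / p * AB;  // P - A with P = (aA+bB)/p
  double PB = a / p * AB;   // P - B
  auto idx = [&](int i, int j, int t) {
    return (size_t)(i * (lb + 1) + j) * (la + lb + 1) + t;
  };
  E.v[idx(0, 0, 0)] = std::exp(-mu * AB * AB);
  // build up in i then j
  for (int i = 1; i <= la; ++i)
    for (int t = 0; t <= i; ++t) {
      double val = 0.0;
      if (t - 1 >= 0) val += E.get(i - 1, 0, t - 1) / (2.0 * p);
      val += PA * E.get(i - 1, 0, t);
      val += (t + 1) * E.get(i - 1, 0, t + 1);
      E.v[idx(i, 0, t)] = val;
    }
  for (int j = 1; j <= lb; ++j)
    for (int i = 0; i <= la; ++i)
      for (int t = 0; t <= i + j; ++t) {
        double val = 0.0;
        if (t - 1 >= 0) val += E.get(i, j - 1, t - 1) / (2.0 * p);
        val += PB * E.get(i, j - 1, t);
        val += (t + 1) * E.get(i, j - 1, t + 1);
        E.v[idx(i, j, t)] = val;
      }
}

// ---------------------------------------------------------------------------
// Hermite Coulomb integrals R_{tuv} = R^0_{tuv}(p, PC).
struct Rtab {
  int L;
  std::vector<double> v;  // [t][u][v] flattened, (L+1)^3
  inline double get(int t, int u, int w) const {
    if (t < 0 || u < 0 || w < 0) return 0.0;
    return v[((size_t)t * (L + 1) + u) * (L + 1) + w];
  }
};

static void build_R(Rtab& R, int L, double p, double X, double Y, double Z) {
  R.L = L;
  int n1 = L + 1;
  R.v.assign((size_t)n1 * n1 * n1, 0.0);
  std::vector<double> F(L + 1);
  boys(L, p * (X * X + Y * Y + Z * Z), F.data());
  // R^n_{000} = (-2p)^n F_n
  // recursion in auxiliary order n; store full (t,u,v,n) table transiently
  std::vector<double> cur((size_t)n1 * n1 * n1 * n1, 0.0);
  auto id4 = [&](int t, int u, int w, int n) {
    return (((size_t)t * n1 + u) * n1 + w) * n1 + n;
  };
  double pw = 1.0;
  for (int n = 0; n <= L; ++n) { cur[id4(0, 0, 0, n)] = pw * F[n]; pw *= -2.0 * p; }
  for (int tot = 1; tot <= L; ++tot) {
    for (int t = 0; t <= tot; ++t)
      for (int u = 0; u + t <= tot; ++u) {
        int w = tot - t - u;
        for (int n = 0; n + tot <= L; ++n) {
          double val = 0.0;
          if (t > 0) {
            if (t > 1) val += (t - 1) * cur[id4(t - 2, u, w, n + 1)];
            val += X * cur[id4(t - 1, u, w, n + 1)];
          } else if (u > 0) {
            if (u > 1) val += (u - 1) * cur[id4(t, u - 2, w, n + 1)];
            val += Y * cur[id4(t, u - 1, w, n + 1)];
          } else {
            if (w > 1) val += (w - 1) * cur[id4(t, u, w - 2, n + 1)];
            val += Z * cur[id4(t, u, w - 1, n + 1)];
          }
          cur[id4(t, u, w, n)] = val;
        }
      }
  }
  for (int t = 0; t <= L; ++t)
    for (int u = 0; u <= L; ++u)
      for (int w = 0; w <= L; ++w)
        if (t + u + w <= L)
          R.v[((size_t)t * n1 + u) * n1 + w] = cur[id4(t, u, w, 0)];
}

// ---------------------------------------------------------------------------
// Shell bookkeeping: cartesian components of angular momentum l, ordered
// (lx,ly,lz) with lx descending, then ly descending.
static int ncart(int l) { return (l + 1) * (l + 2) / 2; }

static void cart_components(int l, std::vector<std::array<int, 3>>& comp) {
  comp.clear();
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly)
      comp.push_back({lx, ly, l - lx - ly});
}

struct ShellSet {
  std::vector<int> l;
  std::vector<double> cx, cy, cz;
  std::vector<int> pstart;           // primitive offsets, length nshell+1
  std::vector<double> exps, coefs;
  std::vector<int> aostart;          // AO offsets
  int nao;
};

static ShellSet parse_shells(const List& sh) {
  ShellSet S;
  IntegerVector l = sh["l"];
  NumericMatrix cen = sh["center"];
  IntegerVector ps = sh["pstart"];
  NumericVector ex = sh["exps"], co = sh["coefs"];
  int n = l.size();
  S.l.assign(l.begin(), l.end());
  S.cx.resize(n); S.cy.resize(n); S.cz.resize(n);
  for (int i = 0; i < n; ++i) { S.cx[i] = cen(i, 0); S.cy[i] = cen(i, 1); S.cz[i] = cen(i, 2); }
  S.pstart.assign(ps.begin(), ps.end());
  S.exps.assign(ex.begin(), ex.end());
  S.coefs.assign(co.begin(), co.end());
  S.aostart.resize(n + 1);
  S.aostart[0] = 0;
  for (int i = 0; i < n; ++i) S.aostart[i + 1] = S.aostart[i] + ncart(S.l[i]);
  S.nao = S.aostart[n];
  return S;
}

// ---------------------------------------------------------------------------
// One-electron integrals
// [[Rcpp::export(name = "cpp_overlap")]]
NumericMatrix cpp_overlap(List shells) {
  ShellSet S = parse_shells(shells);
  int ns = S.l.size();
  NumericMatrix out(S.nao, S.nao);
  std::vector<std::array<int, 3>> ca, cb;
  for (int si = 0; si < ns; ++si)
    for (int sj = 0; sj <= si; ++sj) {
      cart_components(S.l[si], ca);
      cart_components(S.l[sj], cb);
      for (int pi = S.pstart[si]; pi < S.pstart[si + 1]; ++pi)
        for (int pj = S.pstart[sj]; pj < S.pstart[sj + 1]; ++pj) {
          double a = S.exps[pi], b = S.exps[pj];
          double cc = S.coefs[pi] * S.coefs[pj];
          double p = a + b, fac = std::pow(PI / p, 1.5) * cc;
          Etab Ex, Ey, Ez;
          build_E(Ex, S.l[si], S.l[sj], a, b, S.cx[si], S.cx[sj]);
          build_E(Ey, S.l[si], S.l[sj], a, b, S.cy[si], S.cy[sj]);
          build_E(Ez, S.l[si], S.l[sj], a, b, S.cz[si], S.cz[sj]);
          for (size_t ia = 0; ia < ca.size(); ++ia)
            for (size_t ib = 0; ib < cb.size(); ++ib) {
              double v = Ex.get(ca[ia][0], cb[ib][0], 0) *
                         Ey.get(ca[ia][1], cb[ib][1], 0) *
                         Ez.get(ca[ia][2], cb[ib][2], 0) * fac;
              out(S.aostart[si] + ia, S.aostart[sj] + ib) += v;
            }
        }
    }
  for (int i = 0; i < S.nao; ++i)
    for (int j = 0; j < i; ++j) out(j, i) = out(i, j);
  return out;
}

// kinetic energy: 1D factor T_ij = -2b^2 S_{i,j+2} + b(2j+1) S_ij - j(j-1)/2 S_{i,j-2}
// [[Rcpp::export(name = "cpp_kinetic")]]
NumericMatrix cpp_kinetic(List shells) {
  ShellSet S = parse_shells(shells);
  int ns = S.l.size();
  NumericMatrix out(S.nao, S.nao);
  std::vector<std::array<int, 3>> ca, cb;
  for (int si = 0; si < ns; ++si)
    for (int sj = 0; sj < ns; ++sj) {
      cart_components(S.l[si], ca);
      cart_components(S.l[sj], cb);
      for (int pi = S.pstart[si]; pi < S.pstart[si + 1]; ++pi)
        for (int pj = S.pstart[sj]; pj < S.pstart[sj + 1]; ++pj) {
          double a = S.exps[pi], b = S.exps[pj];
          double cc = S.coefs[pi] * S.coefs[pj];
          double p = a + b, fac = std::pow(PI / p, 1.5) * cc;
          Etab Ex, Ey, Ez;
          // need ket angular momentum up to lb+2
          build_E(Ex, S.l[si], S.l[sj] + 2, a, b, S.cx[si], S.cx[sj]);
          build_E(Ey, S.l[si], S.l[sj] + 2, a, b, S.cy[si], S.cy[sj]);
          build_E(Ez, S.l[si], S.l[sj] + 2, a, b, S.cz[si], S.cz[sj]);
          auto S1 = [&](const Etab& E, int i, int j) {
            if (j < 0) return 0.0;
            return E.get(i, j, 0);
          };
          auto T1 = [&](const Etab& E, int i, int j) {
            double t = -2.0 * b * b * S1(E, i, j + 2) +
                       b * (2.0 * j + 1.0) * S1(E, i, j);
            if (j >= 2) t -= 0.5 * j * (j - 1.0) * S1(E, i, j - 2);
            return t;
          };
          for (size_t ia = 0; ia < ca.size(); ++ia)
            for (size_t ib = 0; ib < cb.size(); ++ib) {
              int i1 = ca[ia][0], i2 = ca[ia][1], i3 = ca[ia][2];
              int j1 = cb[ib][0], j2 = cb[ib][1], j3 = cb[ib][2];
              double v = T1(Ex, i1, j1) * S1(Ey, i2, j2) * S1(Ez, i3, j3) +
                         S1(Ex, i1, j1) * T1(Ey, i2, j2) * S1(Ez, i3, j3) +
                         S1(Ex, i1, j1) * S1(Ey, i2, j2) * T1(Ez, i3, j3);
              out(S.aostart[si] + ia, S.aostart[sj] + ib) += v * fac;
            }
        }
    }
  return out;
}

// [[Rcpp::export(name = "cpp_nuclear")]]
NumericMatrix cpp_nuclear(List shells, NumericMatrix atom_xyz,
                          NumericVector atom_z) {
  ShellSet S = parse_shells(shells);
  int ns = S.l.size(), nat = atom_z.size();
  NumericMatrix out(S.nao, S.nao);
  std::vector<std::array<int, 3>> ca, cb;
  for (int si = 0; si < ns; ++si)
    for (int sj = 0; sj <= si; ++sj) {
      int la = S.l[si], lb = S.l[sj], L = la + lb;
      cart_components(la, ca);
      cart_components(lb, cb);
      for (int pi = S.pstart[si]; pi < S.pstart[si + 1]; ++pi)
        for (int pj = S.pstart[sj]; pj < S.pstart[sj + 1]; ++pj) {
          double a = S.exps[pi], b = S.exps[pj];
          double cc = S.coefs[pi] * S.coefs[pj];
          double p = a + b;
          double Px = (a * S.cx[si] + b * S.cx[sj]) / p;
          double Py = (a * S.cy[si] + b * S.cy[sj]) / p;
          double Pz = (a * S.cz[si] + b * S.cz[sj]) / p;
          Etab Ex, Ey, Ez;
          build_E(Ex, la, lb, a, b, S.cx[si], S.cx[sj]);
          build_E(Ey, la, lb, a, b, S.cy[si], S.cy[sj]);
          build_E(Ez, la, lb, a, b, S.cz[si], S.cz[sj]);
          for (int at = 0; at < nat; ++at) {
            Rtab R;
            build_R(R, L, p, Px - atom_xyz(at, 0), Py - atom_xyz(at, 1),
                    Pz - atom_xyz(at, 2));
            double fac = -atom_z[at] * 2.0 * PI / p * cc;
            for (size_t ia = 0; ia < ca.size(); ++ia)
              for (size_t ib = 0; ib < cb.size(); ++ib) {
                double v = 0.0;
                for (int t = 0; t <= ca[ia][0] + cb[ib][0]; ++t)
                  for (int u = 0; u <= ca[ia][1] + cb[ib][1]; ++u)
                    for (int w = 0; w <= ca[ia][2] + cb[ib][2]; ++w)
                      v += Ex.get(ca[ia][0], cb[ib][0], t) *
                           Ey.get(ca[ia][1], cb[ib][1], u) *
                           Ez.get(ca[ia][2], cb[ib][2], w) * R.get(t, u, w);
                out(S.aostart[si] + ia, S.aostart[sj] + ib) += v * fac;
              }
          }
        }
    }
  for (int i = 0; i < S.nao; ++i)
    for (int j = 0; j < i; ++j) out(j, i) = out(i, j);
  return out;
}

// ---------------------------------------------------------------------------
// Electron repulsion. Generic primitive-pair Hermite machinery shared by the
// 4-, 3- and 2-center variants (the latter via dummy s-shells).

// contract one shell pair into Hermite space: returns, per cartesian pair
// (ia,ib), the coefficients over (t,u,v).
struct HermitePair {
  int la, lb, L;
  double p, Px, Py, Pz;
  std::vector<double> coef;  // [ia*ncb+ib][(t*(L+1)+u)*(L+1)+v]
};

static void build_hermite_pair(HermitePair& H, int la, int lb, double a,
                               double b, double cc, const double* A,
                               const double* B) {
  H.la = la; H.lb = lb; H.L = la + lb;
  H.p = a + b;
  H.Px = (a * A[0] + b * B[0]) / H.p;
  H.Py = (a * A[1] + b * B[1]) / H.p;
  H.Pz = (a * A[2] + b * B[2]) / H.p;
  Etab Ex, Ey, Ez;
  build_E(Ex, la, lb, a, b, A[0], B[0]);
  build_E(Ey, la, lb, a, b, A[1], B[1]);
  build_E(Ez, la, lb, a, b, A[2], B[2]);
  std::vector<std::array<int, 3>> ca, cb;
  cart_components(la, ca);
  cart_components(lb, cb);
  int n1 = H.L + 1;
  H.coef.assign(ca.size() * cb.size() * (size_t)n1 * n1 * n1, 0.0);
  size_t stride = (size_t)n1 * n1 * n1;
  for (size_t ia = 0; ia < ca.size(); ++ia)
    for (size_t ib = 0; ib < cb.size(); ++ib) {
      double* dst = &H.coef[(ia * cb.size() + ib) * stride];
      for (int t = 0; t <= ca[ia][0] + cb[ib][0]; ++t)
        for (int u = 0; u <= ca[ia][1] + cb[ib][1]; ++u)
          for (int w = 0; w <= ca[ia][2] + cb[ib][2]; ++w)
            dst[((size_t)t * n1 + u) * n1 + w] =
                cc * Ex.get(ca[ia][0], cb[ib][0], t) *
                Ey.get(ca[ia][1], cb[ib][1], u) *
                Ez.get(ca[ia][2], cb[ib][2], w);
    }
}

// (ab|cd) block for a primitive quartet, accumulated into out[nab x ncd]
static void prim_eri_block(const HermitePair& Hab, const HermitePair& Hcd,
                           std::vector<double>& out) {
  int L = Hab.L + Hcd.L;
  Rtab R;
  double alpha = Hab.p * Hcd.p / (Hab.p + Hcd.p);
  build_R(R, L, alpha, Hab.Px - Hcd.Px, Hab.Py - Hcd.Py, Hab.Pz - Hcd.Pz);
  double fac = 2.0 * std::pow(PI, 2.5) /
               (Hab.p * Hcd.p * std::sqrt(Hab.p + Hcd.p));
  int nab = ncart(Hab.la) * ncart(Hab.lb);
  int ncd = ncart(Hcd.la) * ncart(Hcd.lb);
  int n1a = Hab.L + 1, n1c = Hcd.L + 1;
  size_t sa = (size_t)n1a * n1a * n1a, sc = (size_t)n1c * n1c * n1c;
  for (int iab = 0; iab < nab; ++iab) {
    const double* ea = &Hab.coef[iab * sa];
    for (int icd = 0; icd < ncd; ++icd) {
      const double* ec = &Hcd.coef[icd * sc];
      double v = 0.0;
      for (int t = 0; t <= Hab.L; ++t)
        for (int u = 0; u <= Hab.L - t; ++u)
          for (int w = 0; w <= Hab.L - t - u; ++w) {
            double eav = ea[((size_t)t * n1a + u) * n1a + w];
            if (eav == 0.0) continue;
            double s = 0.0;
            for (int t2 = 0; t2 <= Hcd.L; ++t2)
              for (int u2 = 0; u2 <= Hcd.L - t2; ++u2)
                for (int w2 = 0; w2 <= Hcd.L - t2 - u2; ++w2) {
                  double ecv = ec[((size_t)t2 * n1c + u2) * n1c + w2];
                  if (ecv == 0.0) continue;
                  double sgn = ((t2 + u2 + w2) % 2) ? -1.0 : 1.0;
                  s += sgn * ecv * R.get(t + t2, u + u2, w + w2);
                }
            v += eav * s;
          }
      out[(size_t)iab * ncd + icd] += fac * v;
    }
  }
}

// full 4-center ERI tensor -- oracle use only, small systems
// [[Rcpp::export(name = "cpp_eri4")]]
NumericVector cpp_eri4(List shells) {
  ShellSet S = parse_shells(shells);
  int ns = S.l.size(), n = S.nao;
  if (n > 40) stop("cpp_eri4 is a desk-scale oracle (n_AO <= 40)");
  NumericVector out((R_xlen_t)n * n * n * n);
  std::vector<double> block;
  double A[3], B[3], C[3], D[3];
  for (int si = 0; si < ns; ++si)
    for (int sj = 0; sj < ns; ++sj)
      for (int sk = 0; sk < ns; ++sk)
        for (int sl = 0; sl < ns; ++sl) {
          int nab = ncart(S.l[si]) * ncart(S.l[sj]);
          int ncd = ncart(S.l[sk]) * ncart(S.l[sl]);
          block.assign((size_t)nab * ncd, 0.0);
          A[0] = S.cx[si]; A[1] = S.cy[si]; A[2] = S.cz[si];
          B[0] = S.cx[sj]; B[1] = S.cy[sj]; B[2] = S.cz[sj];
          C[0] = S.cx[sk]; C[1] = S.cy[sk]; C[2] = S.cz[sk];
          D[0] = S.cx[sl]; D[1] = S.cy[sl]; D[2] = S.cz[sl];
          for (int pi = S.pstart[si]; pi < S.pstart[si + 1]; ++pi)
            for (int pj = S.pstart[sj]; pj < S.pstart[sj + 1]; ++pj) {
              HermitePair Hab;
              build_hermite_pair(Hab, S.l[si], S.l[sj], S.exps[pi], S.exps[pj],
                                 S.coefs[pi] * S.coefs[pj], A, B);
              for (int pk = S.pstart[sk]; pk < S.pstart[sk + 1]; ++pk)
                for (int pl = S.pstart[sl]; pl < S.pstart[sl + 1]; ++pl) {
                  HermitePair Hcd;
                  build_hermite_pair(Hcd, S.l[sk], S.l[sl], S.exps[pk],
                                     S.exps[pl], S.coefs[pk] * S.coefs[pl], C,
                                     D);
                  prim_eri_block(Hab, Hcd, block);
                }
            }
          int na = ncart(S.l[si]), nb = ncart(S.l[sj]);
          int nc = ncart(S.l[sk]), nd = ncart(S.l[sl]);
          for (int ia = 0; ia < na; ++ia)
            for (int ib = 0; ib < nb; ++ib)
              for (int ic = 0; ic < nc; ++ic)
                for (int id = 0; id < nd; ++id) {
                  int mu = S.aostart[si] + ia, nu = S.aostart[sj] + ib;
                  int la_ = S.aostart[sk] + ic, sg = S.aostart[sl] + id;
                  out[((R_xlen_t)mu * n + nu) * n * n + (R_xlen_t)la_ * n + sg] =
                      block[(size_t)(ia * nb + ib) * nc * nd + ic * nd + id];
                }
        }
  out.attr("dim") = IntegerVector::create(n, n, n, n);
  return out;
}

// 3-center (mu nu | P): returns n_ao x n_ao x n_aux array
// [[Rcpp::export(name = "cpp_eri3")]]
NumericVector cpp_eri3(List shells, List aux_shells) {
  ShellSet S = parse_shells(shells);
  ShellSet X = parse_shells(aux_shells);
  int n = S.nao, naux = X.nao;
  NumericVector out((R_xlen_t)n * n * naux);
  std::vector<double> block;
  double A[3], B[3], C[3], D0[3] = {0.0, 0.0, 0.0};
  int ns = S.l.size(), nx = X.l.size();
  for (int si = 0; si < ns; ++si)
    for (int sj = 0; sj <= si; ++sj) {
      A[0] = S.cx[si]; A[1] = S.cy[si]; A[2] = S.cz[si];
      B[0] = S.cx[sj]; B[1] = S.cy[sj]; B[2] = S.cz[sj];
      int na = ncart(S.l[si]), nb = ncart(S.l[sj]);
      // precompute all primitive Hermite pairs of (si,sj)
      std::vector<HermitePair> habs;
      for (int pi = S.pstart[si]; pi < S.pstart[si + 1]; ++pi)
        for (int pj = S.pstart[sj]; pj < S.pstart[sj + 1]; ++pj) {
          habs.emplace_back();
          build_hermite_pair(habs.back(), S.l[si], S.l[sj], S.exps[pi],
                             S.exps[pj], S.coefs[pi] * S.coefs[pj], A, B);
        }
      for (int sp = 0; sp < nx; ++sp) {
        C[0] = X.cx[sp]; C[1] = X.cy[sp]; C[2] = X.cz[sp];
        int nc = ncart(X.l[sp]);
        block.assign((size_t)na * nb * nc, 0.0);
        for (int pk = X.pstart[sp]; pk < X.pstart[sp + 1]; ++pk) {
          HermitePair Hcd;
          // dummy unit s-function with zero exponent as the 4th index
          build_hermite_pair(Hcd, X.l[sp], 0, X.exps[pk], 0.0, X.coefs[pk], C,
                             D0);
          for (auto& Hab : habs) prim_eri_block(Hab, Hcd, block);
        }
        for (int ia = 0; ia < na; ++ia)
          for (int ib = 0; ib < nb; ++ib)
            for (int ic = 0; ic < nc; ++ic) {
              int mu = S.aostart[si] + ia, nu = S.aostart[sj] + ib;
              int P = X.aostart[sp] + ic;
              double v = block[(size_t)(ia * nb + ib) * nc + ic];
              out[(R_xlen_t)P * n * n + (R_xlen_t)nu * n + mu] = v;
              out[(R_xlen_t)P * n * n + (R_xlen_t)mu * n + nu] = v;
            }
      }
    }
  out.attr("dim") = IntegerVector::create(n, n, naux);
  return out;
}

// 2-center Coulomb metric (P|Q)
// [[Rcpp::export(name = "cpp_eri2")]]
NumericMatrix cpp_eri2(List aux_shells) {
  ShellSet X = parse_shells(aux_shells);
  int n = X.nao, nx = X.l.size();
  NumericMatrix out(n, n);
  std::vector<double> block;
  double C[3], Cq[3], D0[3] = {0.0, 0.0, 0.0};
  for (int sp = 0; sp < nx; ++sp)
    for (int sq = 0; sq <= sp; ++sq) {
      C[0] = X.cx[sp]; C[1] = X.cy[sp]; C[2] = X.cz[sp];
      Cq[0] = X.cx[sq]; Cq[1] = X.cy[sq]; Cq[2] = X.cz[sq];
      int na = ncart(X.l[sp]), nb = ncart(X.l[sq]);
      block.assign((size_t)na * nb, 0.0);
      for (int pk = X.pstart[sp]; pk < X.pstart[sp + 1]; ++pk) {
        HermitePair Hab;
        build_hermite_pair(Hab, X.l[sp], 0, X.exps[pk], 0.0, X.coefs[pk], C,
                           D0);
        for (int pl = X.pstart[sq]; pl < X.pstart[sq + 1]; ++pl) {
          HermitePair Hcd;
          build_hermite_pair(Hcd, X.l[sq], 0, X.exps[pl], 0.0, X.coefs[pl], Cq,
                             D0);
          // block is indexed [ia*1+0][ic*1+0] -> [ia][ic]
          std::vector<double> tmp((size_t)na * nb, 0.0);
          prim_eri_block(Hab, Hcd, tmp);
          for (size_t k = 0; k < tmp.size(); ++k) block[k] += tmp[k];
        }
      }
      for (int ia = 0; ia < na; ++ia)
        for (int ib = 0; ib < nb; ++ib) {
          out(X.aostart[sp] + ia, X.aostart[sq] + ib) =
              block[(size_t)ia * nb + ib];
          out(X.aostart[sq] + ib, X.aostart[sp] + ia) =
              block[(size_t)ia * nb + ib];
        }
    }
  return out;
}

// ---------------------------------------------------------------------------
// Basis evaluation on points: values and cartesian gradients, for the XC
// quadrature. Returns list(val, dx, dy, dz), each npts x nao.
// [[Rcpp::export(name = "cpp_eval_basis")]]
List cpp_eval_basis(List shells, NumericMatrix pts) {
  ShellSet S = parse_shells(shells);
  int ns = S.l.size(), np = pts.nrow(), nao = S.nao;
  NumericMatrix val(np, nao), gx(np, nao), gy(np, nao), gz(np, nao);
  std::vector<std::array<int, 3>> comp;
  for (int si = 0; si < ns; ++si) {
    cart_components(S.l[si], comp);
    for (int ip = 0; ip < np; ++ip) {
      double x = pts(ip, 0) - S.cx[si];
      double y = pts(ip, 1) - S.cy[si];
      double z = pts(ip, 2) - S.cz[si];
      double r2 = x * x + y * y + z * z;
      double e = 0.0, de = 0.0;  // radial part and its (-2 alpha) weighted sum
      for (int pi = S.pstart[si]; pi < S.pstart[si + 1]; ++pi) {
        double g = S.coefs[pi] * std::exp(-S.exps[pi] * r2);
        e += g;
        de += -2.0 * S.exps[pi] * g;
      }
      for (size_t ic = 0; ic < comp.size(); ++ic) {
        int i = comp[ic][0], j = comp[ic][1], k = comp[ic][2];
        double px = std::pow(x, i), py = std::pow(y, j), pz = std::pow(z, k);
        double poly = px * py * pz;
        int col = S.aostart[si] + ic;
        val(ip, col) = poly * e;
        double dxp = (i > 0) ? i * std::pow(x, i - 1) * py * pz : 0.0;
        double dyp = (j > 0) ? j * px * std::pow(y, j - 1) * pz : 0.0;
        double dzp = (k > 0) ? k * px * py * std::pow(z, k - 1) : 0.0;
        gx(ip, col) = dxp * e + poly * x * de;
        gy(ip, col) = dyp * e + poly * y * de;
        gz(ip, col) = dzp * e + poly * z * de;
      }
    }
  }
  return List::create(_["val"] = val, _["dx"] = gx, _["dy"] = gy,
                      _["dz"] = gz);
}
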