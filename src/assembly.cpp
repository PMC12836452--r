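// Total-Lagrangian finite-element kernels for the spheroidal-LV sleeve model.
//
// Element: 10-node quadratic tetrahedron (VTK ordering: corners 0-3, midsides
// 4=(01) 5=(12) 6=(02) 7=(03) 8=(13) 9=(23)).  Material: Fung-type
// transversely isotropic deviatoric energy with a volumetric penalty, plus an
// optional fiber-aligned active second Piola-Kirchhoff stress.  The material
// tangent dS/dC is formed by symmetric finite differences on the analytic PK2
// stress; the geometric stiffness is exact.  Follower (pressure) loads on
// quadratic triangular facets get their load stiffness by finite differences
// on the facet load vector.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::mat33;
using arma::vec3;

// ---------------------------------------------------------------------------
// quadrature
// ---------------------------------------------------------------------------

// 14-point degree-5 rule on the reference tetrahedron, weights sum to 1
// (multiply by element volume).  Verified against closed-form monomial
// integrals in the test suite.
static const int NGP = 14;
static double GP_L[NGP][4];   // barycentric coordinates
static double GP_W[NGP];
static bool gp_init_done = false;

static void gp_init() {
  if (gp_init_done) return;
  const double a1 = 0.0673422422100983, b1 = 0.3108859192633005,
               w1 = 0.1126879257180162;
  const double a2 = 0.7217942490673264, b2 = 0.0927352503108912,
               w2 = 0.0734930431163619;
  const double c3 = 0.4544962958743503, d3 = 0.0455037041256497,
               w3 = 0.0425460207770812;
  int k = 0;
  for (int i = 0; i < 4; ++i) {
    for (int j = 0; j < 4; ++j) GP_L[k][j] = (i == j) ? a1 : b1;
    GP_W[k++] = w1;
  }
  for (int i = 0; i < 4; ++i) {
    for (int j = 0; j < 4; ++j) GP_L[k][j] = (i == j) ? a2 : b2;
    GP_W[k++] = w2;
  }
  const int pr[6][2] = {{0,1},{0,2},{0,3},{1,2},{1,3},{2,3}};
  for (int p = 0; p < 6; ++p) {
    for (int j = 0; j < 4; ++j) GP_L[k][j] = d3;
    GP_L[k][pr[p][0]] = c3; GP_L[k][pr[p][1]] = c3;
    GP_W[k++] = w3;
  }
  gp_init_done = true;
}

// tet10 shape functions and derivatives w.r.t. (L2, L3, L4)
static void tet10_shape(const double L[4], double N[10], double dN[10][3]) {
  const double L1 = L[0], L2 = L[1], L3 = L[2], L4 = L[3];
  N[0] = L1 * (2 * L1 - 1); N[1] = L2 * (2 * L2 - 1);
  N[2] = L3 * (2 * L3 - 1); N[3] = L4 * (2 * L4 - 1);
  N[4] = 4 * L1 * L2; N[5] = 4 * L2 * L3; N[6] = 4 * L1 * L3;
  N[7] = 4 * L1 * L4; N[8] = 4 * L2 * L4; N[9] = 4 * L3 * L4;
  // dL1/d(r,s,t) = (-1,-1,-1); dL2 = e1; dL3 = e2; dL4 = e3
  const double d1 = 4 * L1 - 1, d2 = 4 * L2 - 1, d3 = 4 * L3 - 1,
               d4 = 4 * L4 - 1;
  double out[10][3] = {
    {-d1, -d1, -d1},
    { d2, 0, 0},
    { 0, d3, 0},
    { 0, 0, d4},
    { 4 * (L1 - L2), -4 * L2, -4 * L2},
    { 4 * L3, 4 * L2, 0},
    { -4 * L3, 4 * (L1 - L3), -4 * L3},
    { -4 * L4, -4 * L4, 4 * (L1 - L4)},
    { 4 * L4, 0, 4 * L2},
    { 0, 4 * L4, 4 * L3}};
  for (int a = 0; a < 10; ++a)
    for (int j = 0; j < 3; ++j) dN[a][j] = out[a][j];
}

// 6-point degree-4 rule on the reference triangle, weights sum to 1
static const int NGPF = 6;
static double GPF_L[NGPF][3];
static double GPF_W[NGPF];
static bool gpf_init_done = false;

static void gpf_init() {
  if (gpf_init_done) return;
  const double a1 = 0.0915762135097707, b1 = 0.8168475729804585,
               w1 = 0.1099517436553219;
  const double a2 = 0.4459484909159649, b2 = 0.1081030181680702,
               w2 = 0.2233815896780115;
  int k = 0;
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) GPF_L[k][j] = a1;
    GPF_L[k][i] = b1; GPF_W[k++] = w1;
  }
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) GPF_L[k][j] = a2;
    GPF_L[k][i] = b2; GPF_W[k++] = w2;
  }
  gpf_init_done = true;
}

static void tri6_shape(const double L[3], double N[6], double dN[6][2]) {
  const double L1 = L[0], L2 = L[1], L3 = L[2];
  N[0] = L1 * (2 * L1 - 1); N[1] = L2 * (2 * L2 - 1); N[2] = L3 * (2 * L3 - 1);
  N[3] = 4 * L1 * L2; N[4] = 4 * L2 * L3; N[5] = 4 * L1 * L3;
  // params (r,s) = (L2,L3), dL1 = (-1,-1)
  const double d1 = 4 * L1 - 1, d2 = 4 * L2 - 1, d3 = 4 * L3 - 1;
  double out[6][2] = {
    {-d1, -d1}, {d2, 0}, {0, d3},
    {4 * (L1 - L2), -4 * L2}, {4 * L3, 4 * L2}, {-4 * L3, 4 * (L1 - L3)}};
  for (int a = 0; a < 6; ++a)
    for (int j = 0; j < 2; ++j) dN[a][j] = out[a][j];
}

// ---------------------------------------------------------------------------
// constitutive law
// ---------------------------------------------------------------------------

// total second Piola-Kirchhoff stress at a point, and (optionally) the strain
// energy density.  Frame R has columns (fiber, sheet, sheet-normal).
static mat33 pk2_total(const mat33& C, double c, double B1, double B2,
                       double B3, double K, const mat33& R, double Ta,
                       double* W_out) {
  // det and adjugate inverse of the symmetric C, written out to avoid
  // temporaries in this innermost kernel
  const double c00 = C(0, 0), c01 = C(0, 1), c02 = C(0, 2),
               c11 = C(1, 1), c12 = C(1, 2), c22 = C(2, 2);
  const double m00 = c11 * c22 - c12 * c12;
  const double m01 = c02 * c12 - c01 * c22;
  const double m02 = c01 * c12 - c02 * c11;
  const double J2 = c00 * m00 + c01 * m01 + c02 * m02;
  if (!(J2 > 0)) stop("invalid deformation: det(C) <= 0");
  const double J = std::sqrt(J2);
  const double Jm23 = std::pow(J2, -1.0 / 3.0);
  mat33 Cinv;
  Cinv(0, 0) = m00 / J2; Cinv(0, 1) = m01 / J2; Cinv(0, 2) = m02 / J2;
  Cinv(1, 0) = Cinv(0, 1);
  Cinv(1, 1) = (c00 * c22 - c02 * c02) / J2;
  Cinv(1, 2) = (c01 * c02 - c00 * c12) / J2;
  Cinv(2, 0) = Cinv(0, 2); Cinv(2, 1) = Cinv(1, 2);
  Cinv(2, 2) = (c00 * c11 - c01 * c01) / J2;

  // Ebar in the fiber frame: Eh = R^T (Jm23*C - I)/2 R
  mat33 Eh;
  {
    mat33 Ebar = 0.5 * Jm23 * C;
    Ebar(0, 0) -= 0.5; Ebar(1, 1) -= 0.5; Ebar(2, 2) -= 0.5;
    Eh = R.t() * Ebar * R;
  }
  // the transverse-shear entry appears through both symmetric components
  // (2 Eh23^2), which makes Q exactly invariant under rotations about the
  // fiber axis (transverse isotropy)
  const double Q = B1 * Eh(0, 0) * Eh(0, 0)
      + B2 * (Eh(1, 1) * Eh(1, 1) + Eh(2, 2) * Eh(2, 2)
              + 2 * Eh(1, 2) * Eh(1, 2))
      + B3 * (Eh(0, 1) * Eh(0, 1) + Eh(0, 2) * Eh(0, 2));
  const double expQ = std::exp(std::min(Q, 250.0));
  mat33 Sh;
  Sh(0, 0) = 2 * B1 * Eh(0, 0);
  Sh(1, 1) = 2 * B2 * Eh(1, 1);
  Sh(2, 2) = 2 * B2 * Eh(2, 2);
  Sh(1, 2) = Sh(2, 1) = 2 * B2 * Eh(1, 2);
  Sh(0, 1) = Sh(1, 0) = B3 * Eh(0, 1);
  Sh(0, 2) = Sh(2, 0) = B3 * Eh(0, 2);
  Sh *= c * expQ;
  const mat33 Sbar = R * Sh * R.t();
  // tr(Sbar Cbar) with Cbar = Jm23 C
  double trSC = 0;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) trSC += Sbar(i, j) * C(i, j);
  trSC *= Jm23;
  const double pvol = 0.5 * K * (J2 - 1.0);
  mat33 S = Jm23 * Sbar + (pvol - trSC / 3.0) * Cinv;
  if (Ta != 0.0) {
    const vec3 f = R.col(0);
    double Eff = 0;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        Eff += f[i] * 0.5 * (C(i, j) - (i == j ? 1.0 : 0.0)) * f[j];
    const double den = 2.0 * Eff + 1.0;
    if (den <= 1e-8) stop("invalid fiber stretch: 2*Eff + 1 <= 0");
    const double s = Ta / den;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) S(i, j) += s * f[i] * f[j];
  }
  if (W_out) *W_out = c * (expQ - 1.0)
      + 0.5 * K * (0.5 * (J2 - 1.0) - std::log(J));
  return S;
}

// accumulate triplet values into the cached compressed-column slots
// [[Rcpp::export]]
NumericVector accumulate_triplets(const NumericVector& x,
                                  const IntegerVector& pos, int nnz) {
  NumericVector out(nnz);
  const int n = x.size();
  for (int i = 0; i < n; ++i) out[pos[i] - 1] += x[i];
  return out;
}

// [[Rcpp::export]]
arma::mat pk2_stress_cpp(arma::mat C, double c, double B1, double B2,
                         double B3, double K, arma::mat R, double Ta) {
  mat33 Cc = C, Rr = R;
  return pk2_total(Cc, c, B1, B2, B3, K, Rr, Ta, nullptr);
}

// Voigt helpers: order 11,22,33,12,13,23 with engineering shear on strain.
static void voigt_perturb(mat33& C, int k, double h) {
  switch (k) {
    case 0: C(0, 0) += 2 * h; break;
    case 1: C(1, 1) += 2 * h; break;
    case 2: C(2, 2) += 2 * h; break;
    case 3: C(0, 1) += h; C(1, 0) += h; break;
    case 4: C(0, 2) += h; C(2, 0) += h; break;
    case 5: C(1, 2) += h; C(2, 1) += h; break;
  }
}

static void to_voigt_stress(const mat33& S, double out[6]) {
  out[0] = S(0, 0); out[1] = S(1, 1); out[2] = S(2, 2);
  out[3] = S(0, 1); out[4] = S(0, 2); out[5] = S(1, 2);
}

// ---------------------------------------------------------------------------
// element assembly
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List fe_assemble(const arma::mat& nodes, const arma::imat& elems,
                 const arma::vec& u, const arma::mat& matpar,
                 const arma::mat& frames, const arma::vec& Ta,
                 bool want_K) {
  gp_init();
  const int ne = elems.n_rows;
  const int nn = nodes.n_rows;
  vec fint(3 * nn, arma::fill::zeros);
  double Wtot = 0.0;
  double Jmin = 1e30, Jmax = -1e30;

  std::vector<int> Ki, Kj;
  std::vector<double> Kx;
  if (want_K) { Ki.reserve(ne * 900); Kj.reserve(ne * 900); Kx.reserve(ne * 900); }

  // precompute shape data at gauss points
  static double Ns[NGP][10], dNs[NGP][10][3];
  for (int g = 0; g < NGP; ++g) tet10_shape(GP_L[g], Ns[g], dNs[g]);

  mat X(10, 3), xc(10, 3);
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < 10; ++a) {
      int n = elems(e, a);
      for (int j = 0; j < 3; ++j) {
        X(a, j) = nodes(n, j);
        xc(a, j) = nodes(n, j) + u[3 * n + j];
      }
    }
    const double c = matpar(e, 0), B1 = matpar(e, 1), B2 = matpar(e, 2),
                 B3 = matpar(e, 3), K = matpar(e, 4);
    mat33 R;
    for (int j = 0; j < 3; ++j)
      for (int i = 0; i < 3; ++i) R(i, j) = frames(e, 3 * j + i);
    const double Tae = Ta[e];

    mat Ke(30, 30, arma::fill::zeros);
    vec fe(30, arma::fill::zeros);

    for (int g = 0; g < NGP; ++g) {
      // reference Jacobian
      mat33 J0(arma::fill::zeros);
      for (int a = 0; a < 10; ++a)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) J0(i, j) += X(a, i) * dNs[g][a][j];
      const double detJ0 = arma::det(J0);
      if (!(detJ0 > 0)) stop("element %d: non-positive reference Jacobian", e + 1);
      const mat33 J0inv = arma::inv(J0);
      // dN/dX (10 x 3)
      mat dNdX(10, 3);
      for (int a = 0; a < 10; ++a) {
        for (int j = 0; j < 3; ++j) {
          double s = 0;
          for (int k = 0; k < 3; ++k) s += dNs[g][a][k] * J0inv(k, j);
          dNdX(a, j) = s;
        }
      }
      // deformation gradient
      mat33 F = xc.t() * dNdX;  // (3x10)(10x3)
      mat33 C = F.t() * F;
      double Wd;
      mat33 S = pk2_total(C, c, B1, B2, B3, K, R, Tae, &Wd);
      const double dV = GP_W[g] * detJ0 / 6.0;
      Wtot += Wd * dV;
      const double Jloc = std::sqrt(arma::det(C));
      if (Jloc < Jmin) Jmin = Jloc;
      if (Jloc > Jmax) Jmax = Jloc;

      // internal force: f_ai = F_iJ S_JK dNa/dX_K
      mat33 FS = F * S;
      for (int a = 0; a < 10; ++a)
        for (int i = 0; i < 3; ++i)
          fe[3 * a + i] += dV * (FS(i, 0) * dNdX(a, 0) + FS(i, 1) * dNdX(a, 1)
                                 + FS(i, 2) * dNdX(a, 2));

      if (want_K) {
        // material tangent by forward differences on S(C) (adequate for the
        // Newton matrix; the residual itself is analytic)
        const double h = 1e-6;
        mat D(6, 6);
        double v0[6];
        to_voigt_stress(S, v0);
        for (int k = 0; k < 6; ++k) {
          mat33 Cp = C;
          voigt_perturb(Cp, k, h);
          mat33 Sp = pk2_total(Cp, c, B1, B2, B3, K, R, Tae, nullptr);
          double vp[6];
          to_voigt_stress(Sp, vp);
          for (int r = 0; r < 6; ++r) D(r, k) = (vp[r] - v0[r]) / h;
        }
        D = 0.5 * (D + D.t());
        // B matrix (6 x 30): dE in Voigt (11,22,33,2*12,2*13,2*23)
        mat B(6, 30, arma::fill::zeros);
        for (int a = 0; a < 10; ++a) {
          for (int i = 0; i < 3; ++i) {
            const int col = 3 * a + i;
            B(0, col) = F(i, 0) * dNdX(a, 0);
            B(1, col) = F(i, 1) * dNdX(a, 1);
            B(2, col) = F(i, 2) * dNdX(a, 2);
            B(3, col) = F(i, 0) * dNdX(a, 1) + F(i, 1) * dNdX(a, 0);
            B(4, col) = F(i, 0) * dNdX(a, 2) + F(i, 2) * dNdX(a, 0);
            B(5, col) = F(i, 1) * dNdX(a, 2) + F(i, 2) * dNdX(a, 1);
          }
        }
        Ke += dV * (B.t() * D * B);
        // geometric stiffness
        mat GSG = dNdX * S * dNdX.t();  // 10 x 10
        for (int a = 0; a < 10; ++a)
          for (int b = 0; b < 10; ++b) {
            const double v = dV * GSG(a, b);
            Ke(3 * a, 3 * b) += v;
            Ke(3 * a + 1, 3 * b + 1) += v;
            Ke(3 * a + 2, 3 * b + 2) += v;
          }
      }
    }

    // scatter
    for (int a = 0; a < 10; ++a) {
      const int na = elems(e, a);
      for (int i = 0; i < 3; ++i) fint[3 * na + i] += fe[3 * a + i];
    }
    if (want_K) {
      for (int a = 0; a < 10; ++a)
        for (int i = 0; i < 3; ++i) {
          const int gi = 3 * elems(e, a) + i;
          for (int b = 0; b < 10; ++b)
            for (int j = 0; j < 3; ++j) {
              Ki.push_back(gi);
              Kj.push_back(3 * elems(e, b) + j);
              Kx.push_back(Ke(3 * a + i, 3 * b + j));
            }
        }
    }
  }

  List out = List::create(
      Named("fint") = wrap(fint), Named("energy") = Wtot,
      Named("Jmin") = Jmin, Named("Jmax") = Jmax);
  if (want_K) {
    out["Ki"] = wrap(Ki);
    out["Kj"] = wrap(Kj);
    out["Kx"] = wrap(Kx);
  }
  return out;
}

// ---------------------------------------------------------------------------
// per-element field extraction
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List fe_fields(const arma::mat& nodes, const arma::imat& elems,
               const arma::vec& u, const arma::mat& matpar,
               const arma::mat& frames, const arma::vec& Ta) {
  gp_init();
  const int ne = elems.n_rows;
  vec vol0(ne), vold(ne), Eff(ne), Jmn(ne), Jmx(ne), Wint(ne), lam(ne);
  mat cauchy(ne, 6);  // volume-averaged Cauchy stress, Voigt 11 22 33 12 13 23
  static double Ns[NGP][10], dNs[NGP][10][3];
  for (int g = 0; g < NGP; ++g) tet10_shape(GP_L[g], Ns[g], dNs[g]);
  mat X(10, 3), xc(10, 3);
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < 10; ++a) {
      int n = elems(e, a);
      for (int j = 0; j < 3; ++j) {
        X(a, j) = nodes(n, j);
        xc(a, j) = nodes(n, j) + u[3 * n + j];
      }
    }
    const double c = matpar(e, 0), B1 = matpar(e, 1), B2 = matpar(e, 2),
                 B3 = matpar(e, 3), K = matpar(e, 4);
    mat33 R;
    for (int j = 0; j < 3; ++j)
      for (int i = 0; i < 3; ++i) R(i, j) = frames(e, 3 * j + i);
    const vec3 f = R.col(0);
    double v0 = 0, vd = 0, ef = 0, wi = 0, jmin = 1e30, jmax = -1e30;
    arma::vec6 sig(arma::fill::zeros);
    for (int g = 0; g < NGP; ++g) {
      mat33 J0(arma::fill::zeros);
      for (int a = 0; a < 10; ++a)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) J0(i, j) += X(a, i) * dNs[g][a][j];
      const double detJ0 = arma::det(J0);
      const mat33 J0inv = arma::inv(J0);
      mat dNdX(10, 3);
      for (int a = 0; a < 10; ++a)
        for (int j = 0; j < 3; ++j) {
          double s = 0;
          for (int k = 0; k < 3; ++k) s += dNs[g][a][k] * J0inv(k, j);
          dNdX(a, j) = s;
        }
      mat33 F = xc.t() * dNdX;
      mat33 C = F.t() * F;
      mat33 E = 0.5 * (C - arma::eye(3, 3));
      double Wd;
      mat33 S = pk2_total(C, c, B1, B2, B3, K, R, Ta[e], &Wd);
      const double dV = GP_W[g] * detJ0 / 6.0;
      const double Jloc = std::sqrt(arma::det(C));
      mat33 T = (F * S * F.t()) / Jloc;
      sig[0] += T(0, 0) * dV; sig[1] += T(1, 1) * dV; sig[2] += T(2, 2) * dV;
      sig[3] += T(0, 1) * dV; sig[4] += T(0, 2) * dV; sig[5] += T(1, 2) * dV;
      v0 += dV; vd += Jloc * dV;
      ef += arma::as_scalar(f.t() * E * f) * dV;
      wi += Wd * dV;
      if (Jloc < jmin) jmin = Jloc;
      if (Jloc > jmax) jmax = Jloc;
    }
    vol0[e] = v0; vold[e] = vd; Eff[e] = ef / v0; Wint[e] = wi;
    Jmn[e] = jmin; Jmx[e] = jmax;
    lam[e] = std::sqrt(std::max(2.0 * Eff[e] + 1.0, 0.0));
    cauchy.row(e) = sig.t() / v0;
  }
  return List::create(Named("vol0") = vol0, Named("vol_def") = vold,
                      Named("Eff") = Eff, Named("W") = Wint,
                      Named("Jmin") = Jmn, Named("Jmax") = Jmx,
                      Named("fiber_stretch") = lam,
                      Named("cauchy") = cauchy);
}

// ---------------------------------------------------------------------------
// follower pressure load on tri6 facets
// ---------------------------------------------------------------------------

// load vector for one facet: f_a = -p * int N_a (g1 x g2) dA_ref, where the
// cross product points along the element-outward normal of the wall.
static void facet_force(const mat& xf, double p, vec& fe) {
  fe.zeros(18);
  static double N[NGPF][6];
  static double dN[NGPF][6][2];
  for (int g = 0; g < NGPF; ++g) tri6_shape(GPF_L[g], N[g], dN[g]);
  for (int g = 0; g < NGPF; ++g) {
    vec3 g1(arma::fill::zeros), g2(arma::fill::zeros);
    for (int a = 0; a < 6; ++a)
      for (int i = 0; i < 3; ++i) {
        g1[i] += xf(a, i) * dN[g][a][0];
        g2[i] += xf(a, i) * dN[g][a][1];
      }
    vec3 nda = arma::cross(g1, g2);  // element-outward, measure included
    const double w = GPF_W[g] * 0.5;
    for (int a = 0; a < 6; ++a)
      for (int i = 0; i < 3; ++i)
        fe[3 * a + i] += -p * N[g][a] * nda[i] * w;
  }
}

// [[Rcpp::export]]
List facet_pressure(const arma::mat& nodes, const arma::imat& facets,
                    const arma::vec& u, double p, bool want_K) {
  gpf_init();
  const int nf = facets.n_rows;
  const int nn = nodes.n_rows;
  vec fext(3 * nn, arma::fill::zeros);
  std::vector<int> Ki, Kj;
  std::vector<double> Kx;
  mat xf(6, 3);
  vec fe(18), fp(18);
  for (int fidx = 0; fidx < nf; ++fidx) {
    for (int a = 0; a < 6; ++a) {
      int n = facets(fidx, a);
      for (int j = 0; j < 3; ++j) xf(a, j) = nodes(n, j) + u[3 * n + j];
    }
    facet_force(xf, p, fe);
    for (int a = 0; a < 6; ++a) {
      int n = facets(fidx, a);
      for (int i = 0; i < 3; ++i) fext[3 * n + i] += fe[3 * a + i];
    }
    if (want_K && p != 0.0) {
      const double h = 1e-7;
      for (int d = 0; d < 18; ++d) {
        mat xp = xf;
        xp(d / 3, d % 3) += h;
        facet_force(xp, p, fp);
        for (int r = 0; r < 18; ++r) {
          // K contribution = -dfext/du; zeros kept so the sparsity pattern
          // is identical across iterations (enables factor reuse)
          Ki.push_back(3 * facets(fidx, r / 3) + r % 3);
          Kj.push_back(3 * facets(fidx, d / 3) + d % 3);
          Kx.push_back(-(fp[r] - fe[r]) / h);
        }
      }
    }
  }
  List out = List::create(Named("fext") = wrap(fext));
  if (want_K) {
    out["Ki"] = wrap(Ki);
    out["Kj"] = wrap(Kj);
    out["Kx"] = wrap(Kx);
  }
  return out;
}

// ---------------------------------------------------------------------------
// geometry helpers
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List tet_volumes(const arma::mat& nodes, const arma::imat& elems) {
  gp_init();
  const int ne = elems.n_rows;
  vec vol(ne), mindet(ne);
  static double Ns[NGP][10], dNs[NGP][10][3];
  for (int g = 0; g < NGP; ++g) tet10_shape(GP_L[g], Ns[g], dNs[g]);
  mat X(10, 3);
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < 10; ++a)
      for (int j = 0; j < 3; ++j) X(a, j) = nodes(elems(e, a), j);
    double v = 0, md = 1e30;
    for (int g = 0; g < NGP; ++g) {
      mat33 J0(arma::fill::zeros);
      for (int a = 0; a < 10; ++a)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) J0(i, j) += X(a, i) * dNs[g][a][j];
      const double d = arma::det(J0);
      v += GP_W[g] * d / 6.0;
      if (d < md) md = d;
    }
    vol[e] = v; mindet[e] = md;
  }
  return List::create(Named("vol") = vol, Named("min_detJ") = mindet);
}

// signed volume contribution of a closed tri6 surface via divergence theorem:
// V = (1/3) * sum int x . (g1 x g2) w/2.  Orientation of facets decides sign.
// [[Rcpp::export]]
double surface_divergence_volume(const arma::mat& nodes,
                                 const arma::imat& facets,
                                 const arma::vec& u) {
  gpf_init();
  static double N[NGPF][6];
  static double dN[NGPF][6][2];
  for (int g = 0; g < NGPF; ++g) tri6_shape(GPF_L[g], N[g], dN[g]);
  double V = 0;
  mat xf(6, 3);
  for (arma::uword fidx = 0; fidx < facets.n_rows; ++fidx) {
    for (int a = 0; a < 6; ++a) {
      int n = facets(fidx, a);
      for (int j = 0; j < 3; ++j) xf(a, j) = nodes(n, j) + u[3 * n + j];
    }
    for (int g = 0; g < NGPF; ++g) {
      vec3 x(arma::fill::zeros), g1(arma::fill::zeros), g2(arma::fill::zeros);
      for (int a = 0; a < 6; ++a)
        for (int i = 0; i < 3; ++i) {
          x[i] += xf(a, i) * N[g][a];
          g1[i] += xf(a, i) * dN[g][a][0];
          g2[i] += xf(a, i) * dN[g][a][1];
        }
      V += GPF_W[g] * 0.5 * arma::dot(x, arma::cross(g1, g2)) / 3.0;
    }
  }
  return V;
}

// monomial integrals over one reference tet10 element mapped by its nodes:
// used by the test suite to certify the quadrature degree.
// [[Rcpp::export]]
double quadrature_monomial(const arma::mat& X10, int px, int py, int pz) {
  gp_init();
  static double Ns[NGP][10], dNs[NGP][10][3];
  for (int g = 0; g < NGP; ++g) tet10_shape(GP_L[g], Ns[g], dNs[g]);
  double acc = 0;
  for (int g = 0; g < NGP; ++g) {
    mat33 J0(arma::fill::zeros);
    vec3 x(arma::fill::zeros);
    for (int a = 0; a < 10; ++a)
      for (int i = 0; i < 3; ++i) {
        x[i] += X10(a, i) * Ns[g][a];
        for (int j = 0; j < 3; ++j) J0(i, j) += X10(a, i) * dNs[g][a][j];
      }
    acc += GP_W[g] * arma::det(J0) / 6.0
        * std::pow(x[0], px) * std::pow(x[1], py) * std::pow(x[2], pz);
  }
  return acc;
}
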