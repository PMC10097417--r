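// Element-level kernels for the bilinear-quad FEM: quadrature basis data,
// total-Lagrangian mechanics residual/tangent with multiplicative growth,
// and the advection-diffusion-reaction operators of the cell-density
// balance assembled on the deformed configuration.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double GP = 0.5773502691896258; // 1/sqrt(3)
// gp order: (-g,-g), (g,-g), (g,g), (-g,g); weights 1
static const double GXI[4] = {-GP, GP, GP, -GP};
static const double GET[4] = {-GP, -GP, GP, GP};

static inline void shape(double xi, double eta, double *N, double *dN) {
  // nodes: (-1,-1), (1,-1), (1,1), (-1,1); dN column-major [4 x 2]
  N[0] = 0.25 * (1 - xi) * (1 - eta);
  N[1] = 0.25 * (1 + xi) * (1 - eta);
  N[2] = 0.25 * (1 + xi) * (1 + eta);
  N[3] = 0.25 * (1 - xi) * (1 + eta);
  dN[0] = -0.25 * (1 - eta); dN[4] = -0.25 * (1 - xi);
  dN[1] =  0.25 * (1 - eta); dN[5] = -0.25 * (1 + xi);
  dN[2] =  0.25 * (1 + eta); dN[6] =  0.25 * (1 + xi);
  dN[3] = -0.25 * (1 + eta); dN[7] =  0.25 * (1 - xi);
}

// Precompute per-quadrature-point reference basis data for the whole mesh.
// Returns shape values, gradients w.r.t. reference coordinates, quadrature
// weights (incl. reference Jacobian), and reference GP positions.
// [[Rcpp::export]]
List cg_gp_basis(const arma::mat &nodes, const arma::imat &elems) {
  const int ne = elems.n_rows, ngp = 4 * ne;
  arma::mat Nsh(ngp, 4), dNdX(ngp, 8), xy(ngp, 2);
  arma::vec w(ngp);
  double N[4], dN[8];
  for (int e = 0; e < ne; ++e) {
    arma::mat X(4, 2);
    for (int a = 0; a < 4; ++a) X.row(a) = nodes.row(elems(e, a) - 1);
    for (int g = 0; g < 4; ++g) {
      shape(GXI[g], GET[g], N, dN);
      arma::mat dNm(dN, 4, 2);
      arma::mat J0 = X.t() * dNm;          // 2x2
      double dj = J0(0, 0) * J0(1, 1) - J0(0, 1) * J0(1, 0);
      arma::mat Jinv(2, 2);
      Jinv(0, 0) =  J0(1, 1) / dj; Jinv(0, 1) = -J0(0, 1) / dj;
      Jinv(1, 0) = -J0(1, 0) / dj; Jinv(1, 1) =  J0(0, 0) / dj;
      arma::mat g_ref = dNm * Jinv;        // 4x2, dNa/dX
      int k = 4 * e + g;
      for (int a = 0; a < 4; ++a) {
        Nsh(k, a) = N[a];
        dNdX(k, 2 * a) = g_ref(a, 0);
        dNdX(k, 2 * a + 1) = g_ref(a, 1);
      }
      w(k) = dj;
      xy.row(k) = N[0] * X.row(0) + N[1] * X.row(1) +
                  N[2] * X.row(2) + N[3] * X.row(3);
    }
  }
  return List::create(_["Nsh"] = Nsh, _["dNdX"] = dNdX, _["w"] = w,
                      _["xy"] = xy);
}

static inline void defgrad(const arma::mat &dNdX, const arma::imat &elems,
                           const arma::vec &u, int e, int g, arma::mat22 &F) {
  int k = 4 * e + g;
  F.eye();
  for (int a = 0; a < 4; ++a) {
    int n = elems(e, a) - 1;
    double ux = u(2 * n), uy = u(2 * n + 1);
    double gx = dNdX(k, 2 * a), gy = dNdX(k, 2 * a + 1);
    F(0, 0) += ux * gx; F(0, 1) += ux * gy;
    F(1, 0) += uy * gx; F(1, 1) += uy * gy;
  }
}

// Total-Lagrangian assembly of the growth-mechanics residual and
// (optionally) consistent tangent. Growth multipliers, fiber directions
// and Lame parameters are supplied per quadrature point. Plane strain
// 2D form of the neo-Hookean law.
// [[Rcpp::export]]
List cg_mech_assemble(const arma::mat &dNdX, const arma::vec &w,
                      const arma::imat &elems, int nnode, const arma::vec &u,
                      const arma::vec &thp, const arma::vec &thr,
                      const arma::mat &Ngp, const arma::vec &mu,
                      const arma::vec &lam, bool want_tangent) {
  const int ne = elems.n_rows;
  arma::vec res(2 * nnode, arma::fill::zeros);
  arma::umat KI; arma::vec KV;
  if (want_tangent) { KI.set_size(2, 64 * ne); KV.set_size(64 * ne); }
  double energy = 0, minDetF = 1e30, minJe = 1e30;
  arma::mat22 F, Fg, Ge, Fe, FeInv, S, P;
  for (int e = 0; e < ne; ++e) {
    double Ke[8][8];
    if (want_tangent) std::memset(Ke, 0, sizeof(Ke));
    for (int g = 0; g < 4; ++g) {
      int k = 4 * e + g;
      defgrad(dNdX, elems, u, e, g, F);
      double dF = F(0, 0) * F(1, 1) - F(0, 1) * F(1, 0);
      if (dF < minDetF) minDetF = dF;
      double tp = thp(k), tr = thr(k);
      double Nx = Ngp(k, 0), Ny = Ngp(k, 1);
      // Fg = tp (I - N@N) + tr N@N ; Ge = Fg^{-1} (symmetric)
      Fg(0, 0) = tp + (tr - tp) * Nx * Nx;
      Fg(1, 1) = tp + (tr - tp) * Ny * Ny;
      Fg(0, 1) = Fg(1, 0) = (tr - tp) * Nx * Ny;
      double itp = 1.0 / tp, itr = 1.0 / tr;
      Ge(0, 0) = itp + (itr - itp) * Nx * Nx;
      Ge(1, 1) = itp + (itr - itp) * Ny * Ny;
      Ge(0, 1) = Ge(1, 0) = (itr - itp) * Nx * Ny;
      double Jg = tp * tr;
      Fe = F * Ge;
      double Je = Fe(0, 0) * Fe(1, 1) - Fe(0, 1) * Fe(1, 0);
      if (Je < minJe) minJe = Je;
      if (Je <= 0 || dF <= 0) continue; // flagged via minDetF/minJe
      FeInv(0, 0) =  Fe(1, 1) / Je; FeInv(0, 1) = -Fe(0, 1) / Je;
      FeInv(1, 0) = -Fe(1, 0) / Je; FeInv(1, 1) =  Fe(0, 0) / Je;
      double lnJe = std::log(Je), m = mu(k), l = lam(k), wk = w(k);
      // S = dpsi/dFe = m (Fe - FeInv^T) + l lnJe FeInv^T
      double cI = l * lnJe - m;
      S(0, 0) = m * Fe(0, 0) + cI * FeInv(0, 0);
      S(0, 1) = m * Fe(0, 1) + cI * FeInv(1, 0);
      S(1, 0) = m * Fe(1, 0) + cI * FeInv(0, 1);
      S(1, 1) = m * Fe(1, 1) + cI * FeInv(1, 1);
      P = Jg * S * Ge; // first Piola-Kirchhoff (Ge symmetric)
      double trFe2 = Fe(0, 0) * Fe(0, 0) + Fe(0, 1) * Fe(0, 1) +
                     Fe(1, 0) * Fe(1, 0) + Fe(1, 1) * Fe(1, 1);
      energy += wk * Jg * (0.5 * l * lnJe * lnJe +
                           0.5 * m * (trFe2 - 2 - 2 * lnJe));
      // intermediate-configuration gradients ga = Ge * dNa
      double ga[4][2], pa[4][2];
      for (int a = 0; a < 4; ++a) {
        double gx = dNdX(k, 2 * a), gy = dNdX(k, 2 * a + 1);
        ga[a][0] = Ge(0, 0) * gx + Ge(0, 1) * gy;
        ga[a][1] = Ge(1, 0) * gx + Ge(1, 1) * gy;
        // pa_i = FeInv(M,i) ga_M
        pa[a][0] = FeInv(0, 0) * ga[a][0] + FeInv(1, 0) * ga[a][1];
        pa[a][1] = FeInv(0, 1) * ga[a][0] + FeInv(1, 1) * ga[a][1];
        int n = elems(e, a) - 1;
        res(2 * n)     += wk * (P(0, 0) * gx + P(0, 1) * gy);
        res(2 * n + 1) += wk * (P(1, 0) * gx + P(1, 1) * gy);
      }
      if (want_tangent) {
        double c2 = m - l * lnJe, wJg = wk * Jg;
        for (int a = 0; a < 4; ++a) for (int b = 0; b < 4; ++b) {
          double gg = ga[a][0] * ga[b][0] + ga[a][1] * ga[b][1];
          for (int i = 0; i < 2; ++i) for (int kk = 0; kk < 2; ++kk) {
            double v = wJg * ((i == kk ? m * gg : 0.0) +
                              c2 * pa[a][kk] * pa[b][i] +
                              l * pa[a][i] * pa[b][kk]);
            Ke[2 * a + i][2 * b + kk] += v;
          }
        }
      }
    }
    if (want_tangent) {
      int base = 64 * e, q = 0;
      for (int a = 0; a < 4; ++a) for (int i = 0; i < 2; ++i)
        for (int b = 0; b < 4; ++b) for (int kk = 0; kk < 2; ++kk, ++q) {
          KI(0, base + q) = 2 * (elems(e, a) - 1) + i + 1;
          KI(1, base + q) = 2 * (elems(e, b) - 1) + kk + 1;
          KV(base + q) = Ke[2 * a + i][2 * b + kk];
        }
    }
  }
  List out = List::create(_["res"] = res, _["energy"] = energy,
                          _["minDetF"] = minDetF, _["minJe"] = minJe);
  if (want_tangent) {
    out["Ki"] = arma::conv_to<arma::ivec>::from(KI.row(0).t());
    out["Kj"] = arma::conv_to<arma::ivec>::from(KI.row(1).t());
    out["Kv"] = KV;
  }
  return out;
}

// Kinematics sweep: per-GP Jacobian of the total deformation gradient and
// the maximum principal stretch (largest singular value) over the mesh.
// [[Rcpp::export]]
List cg_kinematics(const arma::mat &dNdX, const arma::vec &w,
                   const arma::imat &elems, const arma::vec &u) {
  const int ne = elems.n_rows;
  arma::vec Jgp(4 * ne);
  double smax = 0, minDetF = 1e30;
  arma::mat22 F;
  for (int e = 0; e < ne; ++e) for (int g = 0; g < 4; ++g) {
    defgrad(dNdX, elems, u, e, g, F);
    double dF = F(0, 0) * F(1, 1) - F(0, 1) * F(1, 0);
    Jgp(4 * e + g) = dF;
    if (dF < minDetF) minDetF = dF;
    // singular values of 2x2: via C = F^T F eigenvalues (closed form)
    double c11 = F(0, 0) * F(0, 0) + F(1, 0) * F(1, 0);
    double c22 = F(0, 1) * F(0, 1) + F(1, 1) * F(1, 1);
    double c12 = F(0, 0) * F(0, 1) + F(1, 0) * F(1, 1);
    double tr = c11 + c22, disc = std::sqrt(std::max(0.0,
                 0.25 * (c11 - c22) * (c11 - c22) + c12 * c12));
    double lmax = 0.5 * tr + disc;
    double s = std::sqrt(std::max(0.0, lmax));
    if (s > smax) smax = s;
  }
  return List::create(_["Jgp"] = Jgp, _["smax"] = smax,
                      _["minDetF"] = minDetF);
}

// Implicit-Euler operators of the density balance on the (frozen)
// deformed configuration: J-weighted mass matrix, combined
// diffusion - advection + streamline-upwind matrix, and the source
// vector. The migration gate uses the lagged density supplied in cnod.
// [[Rcpp::export]]
List cg_transport_assemble(const arma::mat &Nsh, const arma::mat &dNdX,
                           const arma::vec &w, const arma::imat &elems,
                           int nnode, const arma::vec &u,
                           const arma::vec &cnod, const arma::mat &Ngp,
                           const arma::vec &vprof, const arma::vec &dprof,
                           const arma::vec &rsrc, double c0, double gamma_c,
                           bool supg, const arma::vec &h_elem) {
  const int ne = elems.n_rows;
  const int nt = 16 * ne;
  arma::ivec Ti(nt), Tj(nt);
  arma::vec Mv(nt, arma::fill::zeros), Av(nt, arma::fill::zeros);
  arma::vec Fv(nnode, arma::fill::zeros);
  arma::mat22 F, FinvT;
  for (int e = 0; e < ne; ++e) {
    int nd[4];
    for (int a = 0; a < 4; ++a) nd[a] = elems(e, a) - 1;
    int base = 16 * e, q = 0;
    for (int a = 0; a < 4; ++a) for (int b = 0; b < 4; ++b, ++q) {
      Ti(base + q) = nd[a] + 1; Tj(base + q) = nd[b] + 1;
    }
    for (int g = 0; g < 4; ++g) {
      int k = 4 * e + g;
      defgrad(dNdX, elems, u, e, g, F);
      double J = F(0, 0) * F(1, 1) - F(0, 1) * F(1, 0);
      FinvT(0, 0) =  F(1, 1) / J; FinvT(0, 1) = -F(1, 0) / J;
      FinvT(1, 0) = -F(0, 1) / J; FinvT(1, 1) =  F(0, 0) / J;
      double gx[4], gy[4], cg = 0;
      for (int a = 0; a < 4; ++a) {
        double rx = dNdX(k, 2 * a), ry = dNdX(k, 2 * a + 1);
        gx[a] = FinvT(0, 0) * rx + FinvT(0, 1) * ry;
        gy[a] = FinvT(1, 0) * rx + FinvT(1, 1) * ry;
        cg += Nsh(k, a) * cnod(nd[a]);
      }
      // deformed fiber direction n = F N, migration gate on lagged c
      double nx = F(0, 0) * Ngp(k, 0) + F(0, 1) * Ngp(k, 1);
      double ny = F(1, 0) * Ngp(k, 0) + F(1, 1) * Ngp(k, 1);
      double nn = std::sqrt(nx * nx + ny * ny);
      double z = gamma_c * (cg - c0);
      double gate = (z >= 0) ? 1.0 / (1.0 + std::exp(-z))
                             : std::exp(z) / (1.0 + std::exp(z));
      double vmag = gate * vprof(k);
      double vx = (nn > 0) ? vmag * nx / nn : 0.0;
      double vy = (nn > 0) ? vmag * ny / nn : 0.0;
      double d = dprof(k), wJ = w(k) * J;
      double h = h_elem(e);
      double tau = supg ? h / (2.0 * vmag + 4.0 * d / h + 1e-12) : 0.0;
      double va[4];
      for (int a = 0; a < 4; ++a) va[a] = vx * gx[a] + vy * gy[a];
      q = 0;
      for (int a = 0; a < 4; ++a) {
        Fv(nd[a]) += Nsh(k, a) * rsrc(k) * wJ;
        for (int b = 0; b < 4; ++b, ++q) {
          Mv(base + q) += Nsh(k, a) * Nsh(k, b) * wJ;
          Av(base + q) += (d * (gx[a] * gx[b] + gy[a] * gy[b]) // diffusion
                           - va[a] * Nsh(k, b)                 // advection
                           + tau * va[a] * va[b]) * wJ;        // SU
        }
      }
    }
  }
  return List::create(_["Ti"] = Ti, _["Tj"] = Tj, _["Mv"] = Mv,
                      _["Av"] = Av, _["F"] = Fv);
}

// Element-mean strong residual of the density balance (first-order
// terms) and mean density-gradient norm, for the residual-based
// artificial viscosity of the next step.
// [[Rcpp::export]]
List cg_transport_residual(const arma::mat &Nsh, const arma::mat &dNdX,
                           const arma::vec &w, const arma::imat &elems,
                           const arma::vec &u, const arma::vec &cnew,
                           const arma::vec &cold, double dtinv,
                           const arma::mat &Ngp, const arma::vec &vprof,
                           const arma::vec &rsrc, double c0,
                           double gamma_c) {
  const int ne = elems.n_rows;
  arma::vec Rres(ne, arma::fill::zeros), Rgrad(ne, arma::fill::zeros);
  arma::mat22 F, FinvT;
  for (int e = 0; e < ne; ++e) {
    int nd[4];
    for (int a = 0; a < 4; ++a) nd[a] = elems(e, a) - 1;
    double racc = 0, gacc = 0;
    for (int g = 0; g < 4; ++g) {
      int k = 4 * e + g;
      defgrad(dNdX, elems, u, e, g, F);
      double J = F(0, 0) * F(1, 1) - F(0, 1) * F(1, 0);
      FinvT(0, 0) =  F(1, 1) / J; FinvT(0, 1) = -F(1, 0) / J;
      FinvT(1, 0) = -F(0, 1) / J; FinvT(1, 1) =  F(0, 0) / J;
      double cdot = 0, cg = 0, cgx = 0, cgy = 0;
      for (int a = 0; a < 4; ++a) {
        double rx = dNdX(k, 2 * a), ry = dNdX(k, 2 * a + 1);
        double gxa = FinvT(0, 0) * rx + FinvT(0, 1) * ry;
        double gya = FinvT(1, 0) * rx + FinvT(1, 1) * ry;
        cdot += Nsh(k, a) * (cnew(nd[a]) - cold(nd[a])) * dtinv;
        cg   += Nsh(k, a) * cnew(nd[a]);
        cgx  += gxa * cnew(nd[a]);
        cgy  += gya * cnew(nd[a]);
      }
      double nx = F(0, 0) * Ngp(k, 0) + F(0, 1) * Ngp(k, 1);
      double ny = F(1, 0) * Ngp(k, 0) + F(1, 1) * Ngp(k, 1);
      double nn = std::sqrt(nx * nx + ny * ny);
      double z = gamma_c * (cg - c0);
      double gate = (z >= 0) ? 1.0 / (1.0 + std::exp(-z))
                             : std::exp(z) / (1.0 + std::exp(z));
      double vmag = gate * vprof(k);
      double vx = (nn > 0) ? vmag * nx / nn : 0.0;
      double vy = (nn > 0) ? vmag * ny / nn : 0.0;
      racc += std::abs(cdot + vx * cgx + vy * cgy - rsrc(k));
      gacc += std::sqrt(cgx * cgx + cgy * cgy);
    }
    Rres(e) = 0.25 * racc;
    Rgrad(e) = 0.25 * gacc;
  }
  return List::create(_["res"] = Rres, _["grad"] = Rgrad);
}
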