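// Element kernels for the morphoelastic bilayer problem.
//
// Total reference energy density W(F) = J_g * Psi(A), A = F G^{-1},
// Psi = mu/2 (I1 - 3) - mu ln Je + lambda/2 ln^2 Je  (compressible neo-Hookean).
// Growth G is diagonal and layerwise homogeneous, so it enters per element.
//
// 2D elements are 9-node biquadratic quadrilaterals under plane strain
// (F33 = 1, out-of-plane growth g3 gives A33 = 1/g3). 3D elements are 8-node
// trilinear hexahedra with the lambda (volumetric) term integrated at the
// element centre to relieve locking near nu = 0.5.
//
// The nominal stress and consistent tangent are the exact derivatives of
// J_g * Psi(F G^{-1}) with respect to F:
//   P    = J_g * Pe * G^{-1},            Pe = mu A + (lambda ln Je - mu) A^{-T}
//   dP/dF contracts to, per Gauss point and with H_i = G^{-1} grad N_i,
//   C_i = A^{-T} H_i (per node), beta = lambda ln Je - mu:
//   K[ia,jb] += Jg w |J| ( mu d_ab H_i.H_j + lambda C_ia C_jb - beta C_ib C_ja )

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Quad2D {
  // tensor-product 3-point Gauss, 9-node Lagrange Q2, nodes lexicographic
  // (ix fastest, xi = -1, 0, 1)
  arma::mat pts;   // ngp x 2
  arma::vec wts;   // ngp
  arma::cube dN;   // 9 x 2 x ngp
  Quad2D() {
    const double g = std::sqrt(3.0 / 5.0);
    const double p1[3] = {-g, 0.0, g};
    const double w1[3] = {5.0 / 9.0, 8.0 / 9.0, 5.0 / 9.0};
    pts.set_size(9, 2); wts.set_size(9); dN.set_size(9, 2, 9);
    auto L  = [](int k, double x) {
      if (k == 0) return 0.5 * x * (x - 1.0);
      if (k == 1) return 1.0 - x * x;
      return 0.5 * x * (x + 1.0);
    };
    auto dL = [](int k, double x) {
      if (k == 0) return x - 0.5;
      if (k == 1) return -2.0 * x;
      return x + 0.5;
    };
    int gp = 0;
    for (int jy = 0; jy < 3; ++jy) for (int jx = 0; jx < 3; ++jx, ++gp) {
      const double xi = p1[jx], eta = p1[jy];
      pts(gp, 0) = xi; pts(gp, 1) = eta;
      wts(gp) = w1[jx] * w1[jy];
      for (int iy = 0; iy < 3; ++iy) for (int ix = 0; ix < 3; ++ix) {
        const int i = iy * 3 + ix;
        dN(i, 0, gp) = dL(ix, xi) * L(iy, eta);
        dN(i, 1, gp) = L(ix, xi) * dL(iy, eta);
      }
    }
  }
};

struct Quad3D {
  // 2x2x2 Gauss for the mu part, single centre point for the lambda part;
  // 8-node trilinear hex, nodes lexicographic (ix fastest, xi = -1, 1)
  arma::mat pts; arma::vec wts; arma::cube dN;   // full rule: 8 gp
  arma::cube dN0; double w0;                     // centre point
  Quad3D() {
    const double g = 1.0 / std::sqrt(3.0);
    pts.set_size(8, 3); wts.set_size(8); dN.set_size(8, 3, 8);
    dN0.set_size(8, 3, 1); w0 = 8.0;
    int gp = 0;
    for (int jz = 0; jz < 2; ++jz) for (int jy = 0; jy < 2; ++jy)
      for (int jx = 0; jx < 2; ++jx, ++gp) {
        pts(gp, 0) = (jx ? g : -g); pts(gp, 1) = (jy ? g : -g);
        pts(gp, 2) = (jz ? g : -g);
        wts(gp) = 1.0;
      }
    auto fill = [&](arma::cube &d, double xi, double eta, double zeta, int gp2) {
      for (int iz = 0; iz < 2; ++iz) for (int iy = 0; iy < 2; ++iy)
        for (int ix = 0; ix < 2; ++ix) {
          const int i = iz * 4 + iy * 2 + ix;
          const double sx = ix ? 1.0 : -1.0, sy = iy ? 1.0 : -1.0,
                       sz = iz ? 1.0 : -1.0;
          d(i, 0, gp2) = 0.125 * sx * (1 + sy * eta) * (1 + sz * zeta);
          d(i, 1, gp2) = 0.125 * (1 + sx * xi) * sy * (1 + sz * zeta);
          d(i, 2, gp2) = 0.125 * (1 + sx * xi) * (1 + sy * eta) * sz;
        }
    };
    for (gp = 0; gp < 8; ++gp) fill(dN, pts(gp, 0), pts(gp, 1), pts(gp, 2), gp);
    fill(dN0, 0.0, 0.0, 0.0, 0);
  }
};

const Quad2D &quad2d() { static Quad2D q; return q; }
const Quad3D &quad3d() { static Quad3D q; return q; }

} // namespace

// [[Rcpp::export(name = ".fem_assemble")]]
List fem_assemble(const arma::mat &coords, const arma::imat &conn,
                  const arma::vec &u, const arma::vec &mu,
                  const arma::vec &lambda, const arma::mat &growth,
                  const bool want_tangent) {
  const int dim = coords.n_cols;
  const int nne = conn.n_cols;
  const int ne  = conn.n_rows;
  const int nn  = coords.n_rows;
  const int edof = nne * dim;

  if (!((dim == 2 && nne == 9) || (dim == 3 && nne == 8)))
    stop("unsupported element: dim %d with %d nodes per element", dim, nne);

  arma::vec resid(nn * dim, arma::fill::zeros);
  double energy = 0.0;
  NumericVector tx;
  double *txp = nullptr;
  if (want_tangent) {
    tx = NumericVector((R_xlen_t)ne * edof * edof);
    txp = REAL(tx);
  }

  arma::mat Xe(nne, dim), ue(nne, dim), Ke(edof, edof);
  arma::vec re(edof);
  arma::mat F(dim, dim), A(dim, dim), Ainv(dim, dim), Pe(dim, dim),
            P(dim, dim), dNdX(nne, dim), H(nne, dim), C(nne, dim);
  arma::mat Jm(dim, dim);

  for (int e = 0; e < ne; ++e) {
    for (int i = 0; i < nne; ++i) {
      const int g = conn(e, i) - 1; // R is 1-based
      for (int a = 0; a < dim; ++a) {
        Xe(i, a) = coords(g, a);
        ue(i, a) = u(g * dim + a);
      }
    }
    const double g1 = growth(e, 0), g2 = growth(e, 1), g3 = growth(e, 2);
    const double Jg = g1 * g2 * g3;
    arma::vec ginv(dim);
    ginv(0) = 1.0 / g1; ginv(1) = 1.0 / g2;
    if (dim == 3) ginv(2) = 1.0 / g3;
    const double mue = mu(e), lame = lambda(e);

    Ke.zeros(); re.zeros();
    bool bad = false;

    // one Gauss-point visit; part: 0 = full energy (2D), 1 = mu part,
    // 2 = lambda part (3D split)
    auto visit = [&](const arma::cube &dNc, int gp, double wgt, int part) {
      arma::mat dNdxi(nne, dim);
      for (int i = 0; i < nne; ++i)
        for (int k = 0; k < dim; ++k) dNdxi(i, k) = dNc(i, k, gp);
      Jm = dNdxi.t() * Xe;              // J_{kA} = dX_A/dxi_k
      const double detJ = arma::det(Jm);
      if (detJ <= 0.0) { bad = true; return; }
      dNdX = dNdxi * arma::inv(Jm).t();
      F.eye();
      F += ue.t() * dNdX;               // F_{aA} = d x_a / d X_A
      A = F;
      for (int k = 0; k < dim; ++k) A.col(k) *= ginv(k);
      double Je = arma::det(A);
      double a33sq = 0.0;
      if (dim == 2) { Je /= g3; a33sq = 1.0 / (g3 * g3); }
      if (Je <= 0.0) { bad = true; return; }
      const double lnJe = std::log(Je);
      Ainv = arma::inv(A);
      const double w = wgt * detJ * Jg;

      double I1 = arma::accu(A % A) + (dim == 2 ? a33sq : 0.0);
      double psi;
      double cmu, cbeta, clam; // coefficients entering Pe and the tangent
      if (part == 0) {
        psi = 0.5 * mue * (I1 - 3.0) - mue * lnJe + 0.5 * lame * lnJe * lnJe;
        cmu = mue; cbeta = lame * lnJe - mue; clam = lame;
      } else if (part == 1) {
        psi = 0.5 * mue * (I1 - 3.0) - mue * lnJe;
        cmu = mue; cbeta = -mue; clam = 0.0;
      } else {
        psi = 0.5 * lame * lnJe * lnJe;
        cmu = 0.0; cbeta = lame * lnJe; clam = lame;
      }
      energy += w * psi;

      Pe = cmu * A + cbeta * Ainv.t();
      // residual: r_{ia} += w * (G^{-1} P_e^T)_{A a} dNdX_{iA}
      H = dNdX;
      for (int k = 0; k < dim; ++k) H.col(k) *= ginv(k); // H_i = G^{-1} grad N_i
      re += arma::vectorise((H * Pe.t() * w).t());       // (i,a) interleaved

      if (want_tangent) {
        C = H * Ainv;                                    // C_{ia}
        const arma::mat HH = (w * cmu) * (H * H.t());    // H_i . H_j
        // per-(a,b) blocks: K[ia,jb] += clam C_a C_b^T - cbeta C_b C_a^T
        // (+ delta_ab mu H_i.H_j), scattered with stride `dim`
        for (int a = 0; a < dim; ++a) for (int b = 0; b < dim; ++b) {
          arma::mat blk = (w * clam) * (C.col(a) * C.col(b).t())
                        - (w * cbeta) * (C.col(b) * C.col(a).t());
          if (a == b) blk += HH;
          for (int j = 0; j < nne; ++j) {
            double *kc = Ke.colptr(j * dim + b) + a;
            const double *bc = blk.colptr(j);
            for (int i = 0; i < nne; ++i) kc[i * dim] += bc[i];
          }
        }
      }
    };

    if (dim == 2) {
      const Quad2D &q = quad2d();
      for (int gp = 0; gp < 9 && !bad; ++gp) visit(q.dN, gp, q.wts(gp), 0);
    } else {
      const Quad3D &q = quad3d();
      for (int gp = 0; gp < 8 && !bad; ++gp) visit(q.dN, gp, q.wts(gp), 1);
      if (!bad) visit(q.dN0, 0, q.w0, 2);
    }

    if (bad)
      return List::create(_["ok"] = false, _["bad_element"] = e + 1);

    for (int i = 0; i < nne; ++i) {
      const int g = conn(e, i) - 1;
      for (int a = 0; a < dim; ++a) resid(g * dim + a) += re(i * dim + a);
    }
    if (want_tangent) {
      // row-major (ia, jb) order; the index pattern is rebuilt once on
      // the R side from the connectivity
      double *dst = txp + (size_t)e * edof * edof;
      for (int ia = 0; ia < edof; ++ia)
        for (int jb = 0; jb < edof; ++jb) *dst++ = Ke(ia, jb);
    }
  }

  List out = List::create(_["ok"] = true, _["energy"] = energy,
                          _["resid"] = resid);
  if (want_tangent) out["kx"] = tx;
  return out;
}
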