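// Hex8 elastic-perfectly-plastic FE kernels: B-bar (mean dilatation)
// elements, J2 radial-return with tension/compression yield selection by
// the sign of the trial mean stress, consistent algorithmic tangent,
// and incremental energy bookkeeping.
//
// Voigt conventions: stress [sxx syy szz sxy syz sxz],
// strain (engineering)  [exx eyy ezz gxy gyz gxz].
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double GP = 0.5773502691896257645091488; // 1/sqrt(3)

// corner signs of the standard hex8 ordering
static const int SGN[8][3] = {
  {-1,-1,-1},{ 1,-1,-1},{ 1, 1,-1},{-1, 1,-1},
  {-1,-1, 1},{ 1,-1, 1},{ 1, 1, 1},{-1, 1, 1}};

// dN/dxi at a Gauss point: 8 x 3
static void shape_grad(const double xi[3], mat &dN) {
  for (int a = 0; a < 8; ++a) {
    double sx = SGN[a][0], sy = SGN[a][1], sz = SGN[a][2];
    dN(a,0) = sx * (1 + sy*xi[1]) * (1 + sz*xi[2]) / 8.0;
    dN(a,1) = (1 + sx*xi[0]) * sy * (1 + sz*xi[2]) / 8.0;
    dN(a,2) = (1 + sx*xi[0]) * (1 + sy*xi[1]) * sz / 8.0;
  }
}

// [[Rcpp::export]]
arma::vec fe_hex_volumes(const arma::mat &nodes, const arma::imat &elements) {
  int ne = elements.n_rows;
  vec vols(ne, fill::zeros);
  mat dN(8,3), X(8,3);
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < 8; ++a)
      X.row(a) = nodes.row(elements(e,a) - 1);
    for (int g = 0; g < 8; ++g) {
      double xi[3] = {GP*SGN[g][0], GP*SGN[g][1], GP*SGN[g][2]};
      shape_grad(xi, dN);
      mat J = X.t() * dN;     // 3x3
      vols(e) += det(J);      // unit gauss weights
    }
  }
  return vols;
}

// Full response: internal force, tangent triplets, updated plastic state,
// energy terms. u, eps_p_old, sig_old are the current iterate displacement
// and the *committed* plastic strain / stress of the previous increment.
// [[Rcpp::export]]
Rcpp::List fe_response(const arma::mat &nodes, const arma::imat &elements,
                       const arma::vec &E, const arma::vec &nu,
                       const arma::vec &syc, const arma::vec &syt,
                       const arma::vec &u,
                       const arma::mat &eps_p_old,  // 6 x (8*ne)
                       const arma::mat &sig_old,    // 6 x (8*ne)
                       bool want_matrix) {
  const int ne = elements.n_rows;
  const int ndof = nodes.n_rows * 3;
  vec fint(ndof, fill::zeros);
  mat eps_p_new(6, 8*ne, fill::zeros);
  mat sig_new(6, 8*ne, fill::zeros);
  double E_el = 0.0, D_inc = 0.0, max_ep = 0.0;
  // triplets
  uvec Ki, Kj; vec Kx;
  if (want_matrix) {
    Ki.set_size((size_t)ne*24*24); Kj.set_size((size_t)ne*24*24);
    Kx.set_size((size_t)ne*24*24);
  }
  size_t tp = 0;

  mat dN(8,3), X(8,3);
  cube dNdx_g(8,3,8);           // spatial gradients per gp
  vec detJw(8);
  vec m = {1,1,1,0,0,0};
  // deviatoric projector for engineering Voigt
  mat Idev(6,6, fill::zeros);
  for (int i=0;i<3;++i) for (int j=0;j<3;++j) Idev(i,j) = (i==j?1.0:0.0) - 1.0/3.0;
  for (int i=3;i<6;++i) Idev(i,i) = 0.5;

  for (int e = 0; e < ne; ++e) {
    uvec dofs(24);
    for (int a = 0; a < 8; ++a) {
      int n0 = elements(e,a) - 1;
      X.row(a) = nodes.row(n0);
      for (int d = 0; d < 3; ++d) dofs(3*a+d) = 3*n0 + d;
    }
    // gradients + element volume + mean gradient (B-bar)
    double vol = 0.0;
    mat gbar(8,3, fill::zeros);
    for (int g = 0; g < 8; ++g) {
      double xi[3] = {GP*SGN[g][0], GP*SGN[g][1], GP*SGN[g][2]};
      shape_grad(xi, dN);
      mat J = X.t() * dN;
      double dj = det(J);
      dNdx_g.slice(g) = dN * inv(J);
      detJw(g) = dj;
      vol += dj;
      gbar += dNdx_g.slice(g) * dj;
    }
    gbar /= vol;

    double mu = E(e) / (2.0*(1.0+nu(e)));
    double kap = E(e) / (3.0*(1.0-2.0*nu(e)));
    mat Ke(24,24, fill::zeros);
    vec fe(24, fill::zeros);
    vec ue = u.elem(dofs);

    for (int g = 0; g < 8; ++g) {
      const mat &gx = dNdx_g.slice(g);
      // B-bar matrix 6x24
      mat B(6,24, fill::zeros);
      for (int a = 0; a < 8; ++a) {
        double Nx = gx(a,0), Ny = gx(a,1), Nz = gx(a,2);
        double bx = (gbar(a,0)-Nx)/3.0, by = (gbar(a,1)-Ny)/3.0,
               bz = (gbar(a,2)-Nz)/3.0;
        int c = 3*a;
        B(0,c)   = Nx + bx; B(0,c+1) = by;      B(0,c+2) = bz;
        B(1,c)   = bx;      B(1,c+1) = Ny + by; B(1,c+2) = bz;
        B(2,c)   = bx;      B(2,c+1) = by;      B(2,c+2) = Nz + bz;
        B(3,c)   = Ny;      B(3,c+1) = Nx;
        B(4,c+1) = Nz;      B(4,c+2) = Ny;
        B(5,c)   = Nz;      B(5,c+2) = Nx;
      }
      vec eps = B * ue;
      size_t q = (size_t)e*8 + g;
      vec ee_tr = eps - eps_p_old.col(q);
      // trial stress
      double tr_e = ee_tr(0)+ee_tr(1)+ee_tr(2);
      vec sig_tr(6);
      for (int i=0;i<3;++i) sig_tr(i) = 2.0*mu*(ee_tr(i) - tr_e/3.0) + kap*tr_e;
      for (int i=3;i<6;++i) sig_tr(i) = mu*ee_tr(i);
      double p_tr = (sig_tr(0)+sig_tr(1)+sig_tr(2))/3.0;
      vec s_tr = sig_tr; for (int i=0;i<3;++i) s_tr(i) -= p_tr;
      double sn = std::sqrt(s_tr(0)*s_tr(0)+s_tr(1)*s_tr(1)+s_tr(2)*s_tr(2)
                  + 2.0*(s_tr(3)*s_tr(3)+s_tr(4)*s_tr(4)+s_tr(5)*s_tr(5)));
      // compressive vs tensile yield by the sign of the trial mean stress,
      // blended smoothly over a narrow pressure band (1% of the mean yield)
      // so the residual stays continuous for Newton
      double pb = 0.01 * 0.5 * (syc(e) + syt(e));
      double a = p_tr / pb;
      if (a > 40.0) a = 40.0; else if (a < -40.0) a = -40.0;
      double wcomp = 1.0 / (1.0 + std::exp(a));
      double sy = syt(e) + (syc(e) - syt(e)) * wcomp;
      double f = sn - std::sqrt(2.0/3.0) * sy;
      vec sig = sig_tr;
      vec depv(6, fill::zeros);       // plastic strain incr, engineering Voigt
      mat Dm;
      if (f <= 0.0 || sn < 1e-14) {
        Dm = kap * (m*m.t()) + 2.0*mu * Idev;
        eps_p_new.col(q) = eps_p_old.col(q);
      } else {
        double dg = f / (2.0*mu);
        vec n6 = s_tr / sn;           // tensor components
        for (int i=0;i<6;++i) sig(i) = sig_tr(i) - 2.0*mu*dg*n6(i);
        depv = dg * n6;
        for (int i=3;i<6;++i) depv(i) *= 2.0;   // engineering shear
        eps_p_new.col(q) = eps_p_old.col(q) + depv;
        double th = 1.0 - 2.0*mu*dg/sn;  // = thbar for perfect plasticity
        Dm = kap*(m*m.t()) + 2.0*mu*th*Idev - 2.0*mu*th*(n6*n6.t());
      }
      sig_new.col(q) = sig;
      // energies (weights = detJ, unit gauss weight)
      vec ee = eps - eps_p_new.col(q);
      E_el += 0.5 * dot(sig, ee) * detJw(g);
      D_inc += 0.5 * dot(sig_old.col(q) + sig, depv) * detJw(g);
      double epn = norm(eps_p_new.col(q));
      if (epn > max_ep) max_ep = epn;
      fe += B.t() * sig * detJw(g);
      if (want_matrix) Ke += B.t() * Dm * B * detJw(g);
    }
    fint.elem(dofs) += fe;
    if (want_matrix) {
      for (int i = 0; i < 24; ++i) for (int j = 0; j < 24; ++j) {
        Ki(tp) = dofs(i) + 1; Kj(tp) = dofs(j) + 1; Kx(tp) = Ke(i,j); ++tp;
      }
    }
  }
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("fint") = fint,
    Rcpp::Named("eps_p") = eps_p_new,
    Rcpp::Named("stress") = sig_new,
    Rcpp::Named("E_el") = E_el,
    Rcpp::Named("D_inc") = D_inc,
    Rcpp::Named("max_eps_p") = max_ep);
  if (want_matrix) {
    out["Ki"] = Ki; out["Kj"] = Kj; out["Kx"] = Kx;
  }
  return out;
}
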