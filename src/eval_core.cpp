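// Compiled kernel for the augmented-Lagrangian merit function and its
// analytic gradient. Mirrors the reference R implementation in
// R/transcription.R (eval_core); the two are cross-checked in the test
// suite on random iterates.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Ctx {
  int n, ns, metric; // metric: 0 ncw, 1 ilcw, 2 lew
  bool hs, pointmass, eq7;
  double Tper, D, h, c1, rho, I;
  vec wq, d, lmax;
};

struct Geom {
  mat beta, gamma, l, ux, uy, adx, ady, ld, Dm;
  vec ct, st;
};

rowvec px_of(const vec& q, double D) {
  rowvec px(5);
  px[0] = q[0]; px[1] = q[0] - D / 2;
  px[2] = q[1]; px[3] = q[1] + D; px[4] = q[1] + D / 2;
  return px;
}

Geom geom(const mat& X, const vec& q, const Ctx& c) {
  int m = X.n_rows;
  Geom g;
  vec th = X.col(2), om = X.col(5);
  if (c.pointmass) { th.zeros(); om.zeros(); }
  g.ct = cos(th); g.st = sin(th);
  g.Dm = repmat(c.d.t(), m, 1);
  rowvec px = px_of(q, c.D);
  g.beta = g.Dm.each_col() % g.ct;
  g.beta.each_col() += X.col(0);
  g.beta.each_row() -= px;
  g.gamma = g.Dm.each_col() % g.st;
  g.gamma.each_col() += X.col(1);
  g.l = sqrt(square(g.beta) + square(g.gamma));
  g.l.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });
  g.ux = g.beta / g.l;
  g.uy = g.gamma / g.l;
  g.adx = -(g.Dm.each_col() % (om % g.st));
  g.adx.each_col() += X.col(3);
  g.ady = g.Dm.each_col() % (om % g.ct);
  g.ady.each_col() += X.col(4);
  g.ld = (g.beta % g.adx + g.gamma % g.ady) / g.l;
  return g;
}

// state derivative with respect to stride fraction
mat dyn_G(const mat& X, const mat& U, const Geom& g, const Ctx& c) {
  int m = X.n_rows;
  mat Fm = X.cols(6, 10);
  vec ax = sum(Fm % g.ux, 1);
  vec ay = sum(Fm % g.uy, 1) - 1.0;
  vec al(m, fill::zeros);
  if (!c.pointmass) {
    mat s = g.gamma.each_col() % g.ct;
    s -= g.beta.each_col() % g.st;
    al = sum(g.Dm % Fm % s / g.l, 1) / c.I;
  }
  mat G(m, 12);
  G.col(0) = c.Tper * X.col(3);
  G.col(1) = c.Tper * X.col(4);
  G.col(2) = c.Tper * X.col(5);
  G.col(3) = c.Tper * ax;
  G.col(4) = c.Tper * ay;
  G.col(5) = c.Tper * al;
  G.cols(6, 10) = U;
  G.col(11) = X.col(9);
  return G;
}

struct VJP { mat gX, gU; vec gq; };

// chain through beta = x + d cos(th) - px, gamma = y + d sin(th)
void chain_bg(const Geom& g, const Ctx& c, const mat& dbeta, const mat& dgamma,
              vec& gx, vec& gy, vec& gth, vec& gq) {
  gx += sum(dbeta, 1);
  gy += sum(dgamma, 1);
  if (!c.pointmass) {
    mat t1 = dgamma.each_col() % g.ct;
    t1 -= dbeta.each_col() % g.st;
    gth += sum(g.Dm % t1, 1);
  }
  mat gpx = -dbeta;
  gq[0] += accu(gpx.cols(0, 1));
  gq[1] += accu(gpx.cols(2, 4));
}

VJP dyn_vjp(const mat& X, const Geom& g, const mat& W, const Ctx& c) {
  int m = X.n_rows;
  mat Fm = X.cols(6, 10);
  VJP v;
  v.gX = mat(m, 12, fill::zeros);
  v.gq = vec(2, fill::zeros);
  vec w4 = c.Tper * W.col(3), w5 = c.Tper * W.col(4), w6 = c.Tper * W.col(5);
  mat il3 = 1.0 / pow(g.l, 3);
  mat b2 = square(g.beta), c2 = square(g.gamma), bg = g.beta % g.gamma;
  mat dbeta = Fm % ((c2.each_col() % w4) - (bg.each_col() % w5)) % il3;
  mat dgamma = Fm % ((b2.each_col() % w5) - (bg.each_col() % w4)) % il3;
  mat gF = (g.beta.each_col() % w4 + g.gamma.each_col() % w5) / g.l;
  vec gth_exp(m, fill::zeros);
  if (!c.pointmass) {
    mat s = g.gamma.each_col() % g.ct;
    s -= g.beta.each_col() % g.st;
    vec w6I = w6 / c.I;
    mat Fd = Fm % g.Dm;
    mat l2 = square(g.l);
    mat l2st = l2.each_col() % g.st;
    mat l2ct = l2.each_col() % g.ct;
    dbeta += (Fd.each_col() % w6I) % (-l2st - s % g.beta) % il3;
    dgamma += (Fd.each_col() % w6I) % (l2ct - s % g.gamma) % il3;
    mat dsl = g.Dm % (s / g.l);
    gF += dsl.each_col() % w6I;
    mat t2 = g.gamma.each_col() % g.st;
    t2 += g.beta.each_col() % g.ct;
    gth_exp = sum(Fd % (-t2) / g.l, 1) % w6I;
  }
  vec gx(m, fill::zeros), gy(m, fill::zeros), gth(m, fill::zeros);
  chain_bg(g, c, dbeta, dgamma, gx, gy, gth, v.gq);
  v.gX.col(0) = gx;
  v.gX.col(1) = gy;
  v.gX.col(2) = gth + gth_exp;
  v.gX.cols(6, 10) = gF;
  v.gX.col(3) += c.Tper * W.col(0);
  v.gX.col(4) += c.Tper * W.col(1);
  v.gX.col(5) += c.Tper * W.col(2);
  v.gX.col(9) += W.col(11);
  v.gU = W.cols(6, 10);
  return v;
}

// power terms split by the slacks (m x ns)
mat power_P(const mat& X, const Geom& g, const Ctx& c) {
  mat Fm = X.cols(6, 10);
  if (c.metric == 2) return Fm % g.ld;
  mat pc = Fm % (g.ux.each_col() % X.col(3) + g.uy.each_col() % X.col(4));
  if (c.metric == 1) return pc;
  return sum(pc, 1);
}

VJP power_vjp(const mat& X, const Geom& g, const mat& Wp, const Ctx& c) {
  int m = X.n_rows;
  mat Fm = X.cols(6, 10);
  mat Wl = (c.metric == 0) ? repmat(Wp, 1, 5) : Wp;
  VJP v;
  v.gX = mat(m, 12, fill::zeros);
  v.gq = vec(2, fill::zeros);
  vec gx(m, fill::zeros), gy(m, fill::zeros), gth(m, fill::zeros);
  if (c.metric == 2) {
    mat w = Wl % Fm;
    mat dbeta = w % (g.adx - g.ld % g.ux) / g.l;
    mat dgamma = w % (g.ady - g.ld % g.uy) / g.l;
    mat dadx = w % g.ux;
    mat dady = w % g.uy;
    v.gX.col(3) = sum(dadx, 1);
    v.gX.col(4) = sum(dady, 1);
    if (!c.pointmass) {
      mat t1 = dady.each_col() % g.ct;
      t1 -= dadx.each_col() % g.st;
      v.gX.col(5) = sum(g.Dm % t1, 1);
      mat t2 = dadx.each_col() % g.ct;
      t2 += dady.each_col() % g.st;
      gth = sum(g.Dm % (-t2), 1) % X.col(5);
    }
    chain_bg(g, c, dbeta, dgamma, gx, gy, gth, v.gq);
    v.gX.cols(6, 10) = Wl % g.ld;
  } else {
    mat cd = g.ux.each_col() % X.col(3) + g.uy.each_col() % X.col(4);
    mat w = Wl % Fm;
    mat Ax = -(cd % g.ux);
    Ax.each_col() += X.col(3);
    mat Ay = -(cd % g.uy);
    Ay.each_col() += X.col(4);
    mat dbeta = w % Ax / g.l;
    mat dgamma = w % Ay / g.l;
    v.gX.col(3) = sum(w % g.ux, 1);
    v.gX.col(4) = sum(w % g.uy, 1);
    chain_bg(g, c, dbeta, dgamma, gx, gy, gth, v.gq);
    v.gX.cols(6, 10) = Wl % cd;
  }
  v.gX.col(0) += gx;
  v.gX.col(1) += gy;
  v.gX.col(2) += gth;
  return v;
}

} // namespace

// [[Rcpp::export(name = ".eval_core_cpp")]]
Rcpp::List eval_core_cpp(const arma::vec& z, const Rcpp::List& par,
                         const Rcpp::Nullable<Rcpp::List>& al_,
                         double rho) {
  Ctx c;
  c.n = Rcpp::as<int>(par["n"]);
  c.ns = Rcpp::as<int>(par["ns"]);
  c.metric = Rcpp::as<int>(par["metric_code"]);
  c.hs = Rcpp::as<bool>(par["hs"]);
  c.pointmass = Rcpp::as<bool>(par["pointmass"]);
  c.eq7 = Rcpp::as<bool>(par["eq7"]);
  c.Tper = Rcpp::as<double>(par["Tper"]);
  c.D = Rcpp::as<double>(par["D"]);
  c.h = Rcpp::as<double>(par["h"]);
  c.c1 = Rcpp::as<double>(par["c1"]);
  c.I = Rcpp::as<double>(par["I"]);
  c.wq = Rcpp::as<vec>(par["wq"]);
  c.d = Rcpp::as<vec>(par["d"]);
  c.lmax = Rcpp::as<vec>(par["lmax"]);
  c.rho = rho;
  const int n = c.n, ns = c.ns;
  const int nX = 12 * n, nU = 5 * n, nS = ns * n;
  const int neq = 12 * (n - 1) + nS + 15;
  // unpack
  mat X(const_cast<double*>(z.memptr()), n, 12, false);
  mat U(const_cast<double*>(z.memptr()) + nX, n, 5, false);
  mat SP(const_cast<double*>(z.memptr()) + nX + nU, n, ns, false);
  mat SM(const_cast<double*>(z.memptr()) + nX + nU + nS, n, ns, false);
  vec q = z.subvec(nX + nU + 2 * nS, nX + nU + 2 * nS + 1);

  Geom g = geom(X, q, c);
  mat G = dyn_G(X, U, g, c);
  mat Fm = X.cols(6, 10);
  mat Xm, Um, Gm;
  Geom gm;
  mat Dd;
  if (c.hs) {
    Xm = 0.5 * (X.rows(0, n - 2) + X.rows(1, n - 1)) +
         (c.h / 8.0) * (G.rows(0, n - 2) - G.rows(1, n - 1));
    Um = 0.5 * (U.rows(0, n - 2) + U.rows(1, n - 1));
    gm = geom(Xm, q, c);
    Gm = dyn_G(Xm, Um, gm, c);
    Dd = (X.rows(1, n - 1) - X.rows(0, n - 2)) / c.h -
         (G.rows(0, n - 2) + 4.0 * Gm + G.rows(1, n - 1)) / 6.0;
  } else {
    Dd = (X.rows(1, n - 1) - X.rows(0, n - 2)) / c.h -
         (G.rows(0, n - 2) + G.rows(1, n - 1)) / 2.0;
  }
  mat P = power_P(X, g, c);
  mat ceq_s = SP - SM - P;
  vec bc(15);
  bc[0] = X(0, 0);
  bc[1] = X(n - 1, 0) - c.D / 2;
  for (int j = 1; j <= 5; ++j) bc[1 + j] = X(n - 1, j) - X(0, j);
  bc[7] = X(0, 6);
  bc[8] = X(n - 1, 7);
  bc[9] = X(n - 1, 8);
  bc[10] = X(0, 9);
  bc[11] = X(0, 7) - X(n - 1, 6);
  bc[12] = X(0, 10) - X(n - 1, 9);
  bc[13] = X(0, 8) - X(n - 1, 10);
  bc[14] = X(0, 11);
  vec ceq(neq);
  ceq.subvec(0, 12 * (n - 1) - 1) = vectorise(Dd);
  ceq.subvec(12 * (n - 1), 12 * (n - 1) + nS - 1) = vectorise(ceq_s);
  ceq.subvec(neq - 15, neq - 1) = bc;
  mat Lmax = repmat(c.lmax.t(), n, 1);
  mat eq5 = Fm % (g.l - Lmax);
  vec hip_h = -(X.col(1) + c.d[0] * g.st);
  vec sh_h = -(X.col(1) + c.d[2] * g.st);
  vec cineq(7 * n);
  cineq.subvec(0, 5 * n - 1) = vectorise(eq5);
  cineq.subvec(5 * n, 6 * n - 1) = hip_h;
  cineq.subvec(6 * n, 7 * n - 1) = sh_h;
  // objective
  double work = 2.0 * c.Tper * accu((sum(SP, 1) % c.wq));
  double rate_pen = 2.0 * c.c1 * accu(sum(square(U), 1) % c.wq);
  vec p6 = Fm.col(2) % X.col(11);
  double relax = 2.0 * accu(sum(SP % SM, 1) % c.wq) + 2.0 * accu(c.wq % p6);
  vec p7;
  if (c.eq7) {
    p7 = Fm.col(2) % U.col(3);
    relax += 2.0 * accu(c.wq % square(p7));
  }
  double obj = work + rate_pen + rho * relax;
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("obj") = obj, Rcpp::Named("work") = work,
      Rcpp::Named("rate_pen") = rate_pen,
      Rcpp::Named("relax_pen") = rho * relax,
      Rcpp::Named("ceq") = Rcpp::NumericVector(ceq.begin(), ceq.end()),
      Rcpp::Named("cineq") = Rcpp::NumericVector(cineq.begin(), cineq.end()),
      Rcpp::Named("P") = P, Rcpp::Named("eq5") = eq5,
      Rcpp::Named("p6") = Rcpp::NumericVector(p6.begin(), p6.end()));
  if (al_.isNull()) return out;
  Rcpp::List al(al_);
  double mu = Rcpp::as<double>(al["mu"]);
  vec lam = Rcpp::as<vec>(al["lam"]);
  vec sig = Rcpp::as<vec>(al["sig"]);
  vec weq = lam + mu * ceq;
  vec win = sig + mu * cineq;
  win.transform([](double v) { return v > 0 ? v : 0.0; });
  double merit = obj + dot(lam, ceq) + 0.5 * mu * dot(ceq, ceq) +
                 (dot(win, win) - dot(sig, sig)) / (2.0 * mu);
  // gradient assembly
  mat gX(n, 12, fill::zeros), gU(n, 5, fill::zeros);
  mat gSP(n, ns, fill::zeros), gSM(n, ns, fill::zeros);
  vec gq(2, fill::zeros);
  gSP.each_col() += 2.0 * c.Tper * c.wq;
  gU += 4.0 * c.c1 * (U.each_col() % c.wq);
  gSP += rho * 2.0 * (SM.each_col() % c.wq);
  gSM += rho * 2.0 * (SP.each_col() % c.wq);
  gX.col(8) += rho * 2.0 * (c.wq % X.col(11));
  gX.col(11) += rho * 2.0 * (c.wq % Fm.col(2));
  if (c.eq7) {
    gX.col(8) += rho * 4.0 * (c.wq % p7 % U.col(3));
    gU.col(3) += rho * 4.0 * (c.wq % p7 % Fm.col(2));
  }
  // defects
  mat Wd(weq.memptr(), n - 1, 12, true);
  gX.rows(1, n - 1) += Wd / c.h;
  gX.rows(0, n - 2) -= Wd / c.h;
  mat WG(n, 12, fill::zeros);
  if (c.hs) {
    mat vm = -(4.0 / 6.0) * Wd;
    VJP vj_m = dyn_vjp(Xm, gm, vm, c);
    gX.rows(0, n - 2) += 0.5 * vj_m.gX;
    gX.rows(1, n - 1) += 0.5 * vj_m.gX;
    gU.rows(0, n - 2) += 0.5 * vj_m.gU;
    gU.rows(1, n - 1) += 0.5 * vj_m.gU;
    gq += vj_m.gq;
    WG.rows(0, n - 2) += -Wd / 6.0 + (c.h / 8.0) * vj_m.gX;
    WG.rows(1, n - 1) += -Wd / 6.0 - (c.h / 8.0) * vj_m.gX;
  } else {
    WG.rows(0, n - 2) -= Wd / 2.0;
    WG.rows(1, n - 1) -= Wd / 2.0;
  }
  VJP vj_n = dyn_vjp(X, g, WG, c);
  gX += vj_n.gX;
  gU += vj_n.gU;
  gq += vj_n.gq;
  // slack equalities
  mat Ws(weq.memptr() + 12 * (n - 1), n, ns, true);
  gSP += Ws;
  gSM -= Ws;
  VJP pv = power_vjp(X, g, -Ws, c);
  gX += pv.gX;
  gq += pv.gq;
  // boundary conditions
  const double* w = weq.memptr() + (neq - 15);
  gX(0, 0) += w[0];
  gX(n - 1, 0) += w[1];
  for (int j = 1; j <= 5; ++j) {
    gX(n - 1, j) += w[1 + j];
    gX(0, j) -= w[1 + j];
  }
  gX(0, 6) += w[7];
  gX(n - 1, 7) += w[8];
  gX(n - 1, 8) += w[9];
  gX(0, 9) += w[10];
  gX(0, 7) += w[11]; gX(n - 1, 6) -= w[11];
  gX(0, 10) += w[12]; gX(n - 1, 9) -= w[12];
  gX(0, 8) += w[13]; gX(n - 1, 10) -= w[13];
  gX(0, 11) += w[14];
  // inequalities
  mat W5(win.memptr(), n, 5, true);
  gX.cols(6, 10) += W5 % (g.l - Lmax);
  mat wF5 = W5 % Fm;
  {
    vec gx(n, fill::zeros), gy(n, fill::zeros), gth(n, fill::zeros);
    mat dbeta = wF5 % g.ux, dgamma = wF5 % g.uy;
    chain_bg(g, c, dbeta, dgamma, gx, gy, gth, gq);
    gX.col(0) += gx;
    gX.col(1) += gy;
    gX.col(2) += gth;
  }
  vec w_hip(win.memptr() + 5 * n, n, true);
  vec w_sh(win.memptr() + 6 * n, n, true);
  gX.col(1) -= w_hip + w_sh;
  if (!c.pointmass)
    gX.col(2) -= (w_hip * c.d[0] + w_sh * c.d[2]) % g.ct;
  vec grad(12 * n + 5 * n + 2 * nS + 2);
  grad.subvec(0, nX - 1) = vectorise(gX);
  grad.subvec(nX, nX + nU - 1) = vectorise(gU);
  grad.subvec(nX + nU, nX + nU + nS - 1) = vectorise(gSP);
  grad.subvec(nX + nU + nS, nX + nU + 2 * nS - 1) = vectorise(gSM);
  grad[nX + nU + 2 * nS] = gq[0];
  grad[nX + nU + 2 * nS + 1] = gq[1];
  out["merit"] = merit;
  out["grad"] = Rcpp::NumericVector(grad.begin(), grad.end());
  return out;
}
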