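// Fractional-step (projection) solver for transient incompressible 2D flow
// on a staggered MAC grid with cell masks, variable (regularized Casson)
// viscosity, an implicit Darcy sink in coil cells, and prescribed inlet /
// outlet pressures. Advection is first-order upwind, diffusion explicit;
// the pressure Poisson equation (variable face coefficients from the
// implicit Darcy factor) is solved by warm-started conjugate gradients.
//
// Cell labels: 0 EXTERIOR, 1 FLUID, 2 WALL, 3 COIL. All units SI.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny;
  double dx;
  inline int c(int i, int j) const { return i + nx * j; }
  inline int iu(int i, int j) const { return i + (nx + 1) * j; }
  inline int iv(int i, int j) const { return i + nx * j; }
};

// regularized Casson effective viscosity, capped for explicit stability
inline double casson_mu(double g, double tauY, double muC, double m,
                        double muCap) {
  double fac;
  double mg = m * g;
  if (mg < 1e-24) fac = std::sqrt(tauY * m);
  else fac = std::sqrt(tauY / g) * (1.0 - std::exp(-std::sqrt(mg)));
  double s = std::sqrt(muC) + fac;
  double mu = s * s;
  return std::min(mu, muCap);
}

// linear interpolation in the periodic drive table
inline double drive_at(double t, const std::vector<double>& dt_,
                       const std::vector<double>& dp_, double period) {
  double tt = t - std::floor(t / period) * period;
  size_t n = dt_.size();
  size_t lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    size_t mid = (lo + hi) / 2;
    if (dt_[mid] <= tt) lo = mid; else hi = mid;
  }
  double f = (tt - dt_[lo]) / (dt_[hi] - dt_[lo]);
  return dp_[lo] + f * (dp_[hi] - dp_[lo]);
}

} // namespace

// [[Rcpp::export]]
List cpp_flow_run(IntegerMatrix cellLabel, double dx,
                  NumericMatrix u0, NumericMatrix v0, NumericMatrix p0,
                  double t0, double tEnd, int maxSteps,
                  double rho, double tauY, double muC, double mReg,
                  double muCap,
                  bool coilOn, double Kperm,
                  NumericVector driveTin, NumericVector drivePin,
                  double period,
                  NumericVector sampleTimes, NumericVector osiTimes,
                  NumericVector cycleTimes,
                  double peakWinStart, double peakWinEnd,
                  double safety, double poissonTol, int maxPoissonIters,
                  double uFloor, double dtMax, int fluxEvery) {
  Grid g{cellLabel.nrow(), cellLabel.ncol(), dx};
  const int nx = g.nx, ny = g.ny;
  const int NC = nx * ny, NU = (nx + 1) * ny, NV = nx * (ny + 1);

  std::vector<int> lab(NC);
  std::vector<char> act(NC), coil(NC);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int l = cellLabel(i, j);
      lab[g.c(i, j)] = l;
      act[g.c(i, j)] = (l == 1 || l == 3);
      coil[g.c(i, j)] = (l == 3);
    }

  // face types: 0 fixed-zero, 1 interior, 2 inlet, 3 outlet
  std::vector<char> uT(NU, 0), vT(NV, 0);
  for (int j = 0; j < ny; ++j) {
    for (int i = 1; i < nx; ++i)
      if (act[g.c(i - 1, j)] && act[g.c(i, j)]) uT[g.iu(i, j)] = 1;
    if (act[g.c(0, j)]) uT[g.iu(0, j)] = 2;
    if (act[g.c(nx - 1, j)]) uT[g.iu(nx, j)] = 3;
  }
  for (int j = 1; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (act[g.c(i, j - 1)] && act[g.c(i, j)]) vT[g.iv(i, j)] = 1;

  std::vector<int> actIdx;
  actIdx.reserve(NC);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (act[g.c(i, j)]) actIdx.push_back(g.c(i, j));

  std::vector<double> u(u0.begin(), u0.end()), v(v0.begin(), v0.end()),
      p(p0.begin(), p0.end());
  std::vector<double> us(NU), vs(NV), mu(NC, muC);
  std::vector<double> bx(NU, 1.0), by(NV, 1.0);  // Darcy face factors
  std::vector<double> rhs(NC), rr(NC), zz(NC), qq(NC), diag(NC), pk(NC);
  // 5-point stencil coefficients and IC(0) factor
  std::vector<double> aW(NC), aE(NC), aS(NC), aN(NC);
  std::vector<double> icD(NC, 1.0);
  std::vector<double> pg(NC);

  std::vector<double> dT(driveTin.begin(), driveTin.end());
  std::vector<double> dP(drivePin.begin(), drivePin.end());

  // event bookkeeping
  std::vector<double> sT(sampleTimes.begin(), sampleTimes.end());
  std::vector<double> oT(osiTimes.begin(), osiTimes.end());
  std::vector<double> cT(cycleTimes.begin(), cycleTimes.end());
  std::sort(sT.begin(), sT.end());
  std::sort(oT.begin(), oT.end());
  std::sort(cT.begin(), cT.end());
  size_t iS = 0, iO = 0, iC = 0;
  while (iS < sT.size() && sT[iS] <= t0 + 1e-12) ++iS;
  while (iO < oT.size() && oT[iO] <= t0 + 1e-12) ++iO;
  while (iC < cT.size() && cT[iC] <= t0 + 1e-12) ++iC;

  List stateList, osiList;
  std::vector<double> fluxT, fluxQ, fluxP;
  double t = t0;
  long steps = 0;
  double peakFlux = -1e300, peakT = NA_REAL;
  std::vector<double> peakU, peakV, peakP;
  std::vector<double> prevCycU;  // u at previous cycle boundary
  double cycleDelta = NA_REAL;
  double finalResid = NA_REAL, dtLast = NA_REAL;
  long cgTotal = 0;

  auto snapshotState = [&](double tt) {
    NumericMatrix su(nx + 1, ny), sv(nx, ny + 1), sp(nx, ny);
    std::copy(u.begin(), u.end(), su.begin());
    std::copy(v.begin(), v.end(), sv.begin());
    std::copy(p.begin(), p.end(), sp.begin());
    return List::create(_["u"] = su, _["v"] = sv, _["p"] = sp, _["t"] = tt);
  };

  // ghost-aware tangential fetch for u: neighbour face (i, jn)
  auto uTan = [&](int i, int j, int jn) -> double {
    if (jn >= 0 && jn < ny && uT[g.iu(i, jn)] != 0) return u[g.iu(i, jn)];
    double self = u[g.iu(i, j)];
    if (jn < 0 || jn >= ny) return -self;  // beyond grid: wall
    bool anyAct = false;
    if (i - 1 >= 0 && act[g.c(i - 1, jn)]) anyAct = true;
    if (i <= nx - 1 && i >= 0 && act[g.c(std::min(i, nx - 1), jn)]) anyAct = true;
    return anyAct ? 0.0 : -self;  // stair corner vs plain wall
  };
  auto vTan = [&](int i, int j, int in) -> double {
    if (in >= 0 && in < nx && vT[g.iv(in, j)] != 0) return v[g.iv(in, j)];
    double self = v[g.iv(i, j)];
    if (in < 0 || in >= nx) return self;  // inlet/outlet: zero-gradient
    bool anyAct = false;
    if (j - 1 >= 0 && act[g.c(in, j - 1)]) anyAct = true;
    if (j <= ny - 1 && act[g.c(in, std::min(j, ny - 1))]) anyAct = true;
    return anyAct ? 0.0 : -self;
  };

  const bool darcy = coilOn && R_finite(Kperm) && Kperm > 0;

  while (t < tEnd - 1e-12 && steps < maxSteps) {
    // ---- viscosity field and stable dt --------------------------------
    double umax = uFloor, mumax = muC;
    for (int k = 0; k < NU; ++k)
      if (uT[k]) umax = std::max(umax, std::fabs(u[k]));
    for (int k = 0; k < NV; ++k)
      if (vT[k]) umax = std::max(umax, std::fabs(v[k]));
    if (!R_finite(umax))
      stop("divergence detected (non-finite velocity) at step %ld", steps);

    for (size_t a = 0; a < actIdx.size(); ++a) {
      int cc = actIdx[a];
      int i = cc % nx, j = cc / nx;
      double ux = (u[g.iu(i + 1, j)] - u[g.iu(i, j)]) / dx;
      double vy = (v[g.iv(i, j + 1)] - v[g.iv(i, j)]) / dx;
      // uy + vx averaged over the four cell corners
      double sh = 0.0;
      for (int cj = j; cj <= j + 1; ++cj)
        for (int ci = i; ci <= i + 1; ++ci) {
          // corner (ci, cj): uy from faces (ci, cj-1)-(ci, cj),
          // vx from faces (ci-1, cj)-(ci, cj)
          double uhi = (cj < ny && uT[g.iu(ci, cj)]) ? u[g.iu(ci, cj)] : 0.0;
          double ulo = (cj - 1 >= 0 && uT[g.iu(ci, cj - 1)])
                           ? u[g.iu(ci, cj - 1)] : 0.0;
          if (cj < ny && uT[g.iu(ci, cj)] && !(cj - 1 >= 0 && uT[g.iu(ci, cj - 1)]))
            ulo = -uhi;
          if (!(cj < ny && uT[g.iu(ci, cj)]) && cj - 1 >= 0 && uT[g.iu(ci, cj - 1)])
            uhi = -ulo;
          double vhi = (ci < nx && vT[g.iv(ci, cj)]) ? v[g.iv(ci, cj)] : 0.0;
          double vlo = (ci - 1 >= 0 && vT[g.iv(ci - 1, cj)])
                           ? v[g.iv(ci - 1, cj)] : 0.0;
          if (ci < nx && vT[g.iv(ci, cj)] && !(ci - 1 >= 0 && vT[g.iv(ci - 1, cj)]))
            vlo = -vhi;
          if (!(ci < nx && vT[g.iv(ci, cj)]) && ci - 1 >= 0 && vT[g.iv(ci - 1, cj)])
            vhi = -vlo;
          sh += (uhi - ulo) / dx + (vhi - vlo) / dx;
        }
      sh *= 0.25;
      double gdot = std::sqrt(2.0 * (ux * ux + vy * vy) + sh * sh);
      double m = casson_mu(gdot, tauY, muC, mReg, muCap);
      mu[cc] = m;
      if (m > mumax) mumax = m;
    }

    double dt = safety / (umax / dx + 4.0 * (mumax / rho) / (dx * dx));
    if (dt > dtMax) dt = dtMax;
    // land exactly on the next event
    double nextEv = tEnd;
    if (iS < sT.size()) nextEv = std::min(nextEv, sT[iS]);
    if (iO < oT.size()) nextEv = std::min(nextEv, oT[iO]);
    if (iC < cT.size()) nextEv = std::min(nextEv, cT[iC]);
    if (t + dt > nextEv) dt = nextEv - t;
    if (dt <= 0) dt = 1e-12;
    dtLast = dt;

    double tNew = t + dt;
    double pin = drive_at(tNew, dT, dP, period);

    // ---- Darcy face factors ------------------------------------------
    if (darcy) {
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i <= nx; ++i) {
          int k = g.iu(i, j);
          if (!uT[k]) { bx[k] = 1.0; continue; }
          int cl = std::max(i - 1, 0), cr = std::min(i, nx - 1);
          bool cc = coil[g.c(cl, j)] || coil[g.c(cr, j)];
          if (!cc) { bx[k] = 1.0; continue; }
          double mf = 0.5 * (mu[g.c(cl, j)] + mu[g.c(cr, j)]);
          bx[k] = 1.0 / (1.0 + dt * mf / (rho * Kperm));
        }
      for (int j = 0; j <= ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int k = g.iv(i, j);
          if (!vT[k]) { by[k] = 1.0; continue; }
          int cb = std::max(j - 1, 0), ct = std::min(j, ny - 1);
          bool cc = coil[g.c(i, cb)] || coil[g.c(i, ct)];
          if (!cc) { by[k] = 1.0; continue; }
          double mf = 0.5 * (mu[g.c(i, cb)] + mu[g.c(i, ct)]);
          by[k] = 1.0 / (1.0 + dt * mf / (rho * Kperm));
        }
    }

    // ---- provisional velocities --------------------------------------
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        int k = g.iu(i, j);
        char ty = uT[k];
        if (!ty) { us[k] = 0.0; continue; }
        double uc = u[k];
        // x-neighbours (normal direction)
        double uW, uE;
        if (i - 1 < 0) uW = uc;                       // inlet zero-gradient
        else if (uT[g.iu(i - 1, j)]) uW = u[g.iu(i - 1, j)];
        else uW = 0.0;                                 // wall face
        if (i + 1 > nx) uE = uc;                       // outlet zero-gradient
        else if (uT[g.iu(i + 1, j)]) uE = u[g.iu(i + 1, j)];
        else uE = 0.0;
        double uN = uTan(i, j, j + 1), uS = uTan(i, j, j - 1);
        // advecting v at the u-face
        int cl = std::max(i - 1, 0), cr = std::min(i, nx - 1);
        double vc = 0.25 * (v[g.iv(cl, j)] + v[g.iv(cr, j)] +
                            v[g.iv(cl, j + 1)] + v[g.iv(cr, j + 1)]);
        double dudx = (uc > 0) ? (uc - uW) / dx : (uE - uc) / dx;
        double dudy = (vc > 0) ? (uc - uS) / dx : (uN - uc) / dx;
        double adv = -(uc * dudx + vc * dudy);
        // variable-viscosity diffusion div(mu grad u)
        double muE = mu[g.c(cr, j)], muW = mu[g.c(cl, j)];
        auto cornerMu = [&](int cj) {
          double s = 0; int n = 0;
          for (int ci = cl; ci <= cr; ++ci)
            for (int jj = cj - 1; jj <= cj; ++jj)
              if (jj >= 0 && jj < ny && act[g.c(ci, jj)]) { s += mu[g.c(ci, jj)]; ++n; }
          return n ? s / n : muC;
        };
        double muN = cornerMu(j + 1), muS = cornerMu(j);
        double dif = (muE * (uE - uc) - muW * (uc - uW) +
                      muN * (uN - uc) - muS * (uc - uS)) / (dx * dx);
        double ust = uc + dt * (adv + dif / rho);
        us[k] = darcy ? ust * bx[k] : ust;
      }

    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int k = g.iv(i, j);
        if (!vT[k]) { vs[k] = 0.0; continue; }
        double vc = v[k];
        double vS, vN;
        if (j - 1 < 0) vS = 0.0;
        else if (vT[g.iv(i, j - 1)]) vS = v[g.iv(i, j - 1)];
        else vS = 0.0;
        if (j + 1 > ny) vN = 0.0;
        else if (vT[g.iv(i, j + 1)]) vN = v[g.iv(i, j + 1)];
        else vN = 0.0;
        double vE = vTan(i, j, i + 1), vW = vTan(i, j, i - 1);
        int cb = std::max(j - 1, 0), ct = std::min(j, ny - 1);
        double uc = 0.25 * (u[g.iu(i, cb)] + u[g.iu(i + 1, cb)] +
                            u[g.iu(i, ct)] + u[g.iu(i + 1, ct)]);
        double dvdy = (vc > 0) ? (vc - vS) / dx : (vN - vc) / dx;
        double dvdx = (uc > 0) ? (vc - vW) / dx : (vE - vc) / dx;
        double adv = -(uc * dvdx + vc * dvdy);
        double muN_ = mu[g.c(i, ct)], muS_ = mu[g.c(i, cb)];
        auto cornerMu = [&](int ci) {
          double s = 0; int n = 0;
          for (int jj = cb; jj <= ct; ++jj)
            for (int ii = ci - 1; ii <= ci; ++ii)
              if (ii >= 0 && ii < nx && act[g.c(ii, jj)]) { s += mu[g.c(ii, jj)]; ++n; }
          return n ? s / n : muC;
        };
        double muE_ = cornerMu(i + 1), muW_ = cornerMu(i);
        double dif = (muN_ * (vN - vc) - muS_ * (vc - vS) +
                      muE_ * (vE - vc) - muW_ * (vc - vW)) / (dx * dx);
        double vst = vc + dt * (adv + dif / rho);
        vs[k] = darcy ? vst * by[k] : vst;
      }

    // ---- pressure Poisson: div(beta grad p) = (rho/dt) div(u*) -------
    const double idx2 = 1.0 / (dx * dx);
    for (size_t a = 0; a < actIdx.size(); ++a) {
      int cc = actIdx[a];
      int i = cc % nx, j = cc / nx;
      double div = (us[g.iu(i + 1, j)] - us[g.iu(i, j)] +
                    vs[g.iv(i, j + 1)] - vs[g.iv(i, j)]) / dx;
      double d = 0.0, b = -(rho / dt) * div;
      double w = 0, e = 0, s_ = 0, n_ = 0;
      if (i == 0) { d += 2.0 * idx2; b += 2.0 * idx2 * pin; }
      else if (act[g.c(i - 1, j)]) { w = -bx[g.iu(i, j)] * idx2; d -= w; }
      if (i == nx - 1) { d += 2.0 * idx2; /* outlet p = 0 */ }
      else if (act[g.c(i + 1, j)]) { e = -bx[g.iu(i + 1, j)] * idx2; d -= e; }
      if (j > 0 && act[g.c(i, j - 1)]) { s_ = -by[g.iv(i, j)] * idx2; d -= s_; }
      if (j < ny - 1 && act[g.c(i, j + 1)]) { n_ = -by[g.iv(i, j + 1)] * idx2; d -= n_; }
      aW[cc] = w; aE[cc] = e; aS[cc] = s_; aN[cc] = n_;
      diag[cc] = d;
      rhs[cc] = b;
    }

    // modified incomplete (DILU/MIC) factorization of the 5-point
    // operator: dropped fill is lumped onto the diagonal (Gustafsson),
    // which is markedly stronger than plain IC(0) for Poisson problems
    for (size_t a = 0; a < actIdx.size(); ++a) {
      int cc = actIdx[a];
      double d2 = diag[cc];
      if (aW[cc] != 0)
        d2 -= aW[cc] * (aW[cc] + 0.95 * aN[cc - 1]) / icD[cc - 1];
      if (aS[cc] != 0)
        d2 -= aS[cc] * (aS[cc] + 0.95 * aE[cc - nx]) / icD[cc - nx];
      if (d2 < 0.05 * diag[cc]) d2 = 0.05 * diag[cc];  // breakdown guard
      icD[cc] = d2;
    }

    auto matvec = [&](const std::vector<double>& x, std::vector<double>& ax) {
      for (size_t a = 0; a < actIdx.size(); ++a) {
        int cc = actIdx[a];
        double s = diag[cc] * x[cc];
        if (aW[cc] != 0) s += aW[cc] * x[cc - 1];
        if (aE[cc] != 0) s += aE[cc] * x[cc + 1];
        if (aS[cc] != 0) s += aS[cc] * x[cc - nx];
        if (aN[cc] != 0) s += aN[cc] * x[cc + nx];
        ax[cc] = s;
      }
    };
    // z = (D+L) D^{-1} (D+U) \ r  (forward then backward sweep)
    auto precond = [&](const std::vector<double>& r, std::vector<double>& z) {
      for (size_t a = 0; a < actIdx.size(); ++a) {
        int cc = actIdx[a];
        double s = r[cc];
        if (aW[cc] != 0) s -= aW[cc] * pk[cc - 1];
        if (aS[cc] != 0) s -= aS[cc] * pk[cc - nx];
        pk[cc] = s / icD[cc];
      }
      for (size_t a = actIdx.size(); a-- > 0;) {
        int cc = actIdx[a];
        double s = 0.0;
        if (aE[cc] != 0) s += aE[cc] * z[cc + 1];
        if (aN[cc] != 0) s += aN[cc] * z[cc + nx];
        z[cc] = pk[cc] - s / icD[cc];
      }
    };

    // preconditioned CG, warm-started from the previous pressure
    matvec(p, qq);
    double bn2 = 0.0, rn2 = 0.0;
    for (size_t a = 0; a < actIdx.size(); ++a) {
      int cc = actIdx[a];
      rr[cc] = rhs[cc] - qq[cc];
      bn2 += rhs[cc] * rhs[cc];
      rn2 += rr[cc] * rr[cc];
    }
    double tol2 = poissonTol * poissonTol * std::max(bn2, 1e-300);
    int it = 0;
    if (rn2 > tol2) {
      precond(rr, zz);
      double rho1 = 0.0;
      for (size_t a = 0; a < actIdx.size(); ++a)
        rho1 += rr[actIdx[a]] * zz[actIdx[a]];
      std::vector<double>& dir = pg;  // reuse as search direction
      for (size_t a = 0; a < actIdx.size(); ++a) dir[actIdx[a]] = zz[actIdx[a]];
      for (it = 1; it <= maxPoissonIters; ++it) {
        matvec(dir, qq);
        double zq = 0.0;
        for (size_t a = 0; a < actIdx.size(); ++a)
          zq += dir[actIdx[a]] * qq[actIdx[a]];
        double alpha = rho1 / zq;
        double rn = 0.0;
        for (size_t a = 0; a < actIdx.size(); ++a) {
          int cc = actIdx[a];
          p[cc] += alpha * dir[cc];
          rr[cc] -= alpha * qq[cc];
          rn += rr[cc] * rr[cc];
        }
        if (rn <= tol2) break;
        precond(rr, zz);
        double rho2 = 0.0;
        for (size_t a = 0; a < actIdx.size(); ++a)
          rho2 += rr[actIdx[a]] * zz[actIdx[a]];
        double beta = rho2 / rho1;
        rho1 = rho2;
        for (size_t a = 0; a < actIdx.size(); ++a) {
          int cc = actIdx[a];
          dir[cc] = zz[cc] + beta * dir[cc];
        }
      }
      if (it > maxPoissonIters)
        stop("pressure Poisson failed to converge in %d iterations at step %ld",
             maxPoissonIters, steps);
    }
    cgTotal += it;

    // ---- projection ---------------------------------------------------
    double maxDiv = 0.0;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        int k = g.iu(i, j);
        char ty = uT[k];
        if (!ty) { u[k] = 0.0; continue; }
        double gp;
        if (ty == 2) gp = 2.0 * (p[g.c(0, j)] - pin) / dx;
        else if (ty == 3) gp = 2.0 * (0.0 - p[g.c(nx - 1, j)]) / dx;
        else gp = (p[g.c(i, j)] - p[g.c(i - 1, j)]) / dx;
        u[k] = us[k] - bx[k] * dt / rho * gp;
      }
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int k = g.iv(i, j);
        if (!vT[k]) { v[k] = 0.0; continue; }
        double gp = (p[g.c(i, j)] - p[g.c(i, j - 1)]) / dx;
        v[k] = vs[k] - by[k] * dt / rho * gp;
      }
    for (size_t a = 0; a < actIdx.size(); ++a) {
      int cc = actIdx[a];
      int i = cc % nx, j = cc / nx;
      double div = std::fabs(u[g.iu(i + 1, j)] - u[g.iu(i, j)] +
                             v[g.iv(i, j + 1)] - v[g.iv(i, j)]) / dx;
      if (div > maxDiv) maxDiv = div;
    }

    t = tNew;
    ++steps;
    finalResid = maxDiv * dx / std::max(umax, uFloor);

    // inlet volumetric flux (per unit depth)
    double flux = 0.0;
    for (int j = 0; j < ny; ++j)
      if (uT[g.iu(0, j)]) flux += u[g.iu(0, j)] * dx;
    if (steps % fluxEvery == 0 || steps == 1) {
      fluxT.push_back(t); fluxQ.push_back(flux); fluxP.push_back(pin);
    }

    if (t >= peakWinStart - 1e-12 && t <= peakWinEnd + 1e-12 &&
        flux > peakFlux) {
      peakFlux = flux; peakT = t;
      peakU = u; peakV = v; peakP = p;
    }

    while (iS < sT.size() && t >= sT[iS] - 1e-12) {
      stateList.push_back(snapshotState(t));
      ++iS;
    }
    while (iO < oT.size() && t >= oT[iO] - 1e-12) {
      NumericMatrix su(nx + 1, ny), sv(nx, ny + 1);
      std::copy(u.begin(), u.end(), su.begin());
      std::copy(v.begin(), v.end(), sv.begin());
      osiList.push_back(List::create(_["u"] = su, _["v"] = sv, _["t"] = t));
      ++iO;
    }
    while (iC < cT.size() && t >= cT[iC] - 1e-12) {
      if (!prevCycU.empty()) {
        double num = 0.0, den = 0.0;
        for (int k = 0; k < NU; ++k) {
          double d = u[k] - prevCycU[k];
          num += d * d; den += u[k] * u[k];
        }
        cycleDelta = std::sqrt(num) / std::max(std::sqrt(den), 1e-300);
      }
      prevCycU = u;
      ++iC;
    }

    if (steps % 25 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix uo(nx + 1, ny), vo(nx, ny + 1), po(nx, ny);
  std::copy(u.begin(), u.end(), uo.begin());
  std::copy(v.begin(), v.end(), vo.begin());
  std::copy(p.begin(), p.end(), po.begin());

  List peak = R_NilValue;
  if (peakFlux > -1e299) {
    NumericMatrix pu(nx + 1, ny), pv(nx, ny + 1), pp(nx, ny);
    std::copy(peakU.begin(), peakU.end(), pu.begin());
    std::copy(peakV.begin(), peakV.end(), pv.begin());
    std::copy(peakP.begin(), peakP.end(), pp.begin());
    peak = List::create(_["u"] = pu, _["v"] = pv, _["p"] = pp,
                        _["t"] = peakT, _["flux"] = peakFlux);
  }

  return List::create(
      _["u"] = uo, _["v"] = vo, _["p"] = po, _["t"] = t,
      _["steps"] = (double)steps,
      _["states"] = stateList, _["peak"] = peak, _["osi"] = osiList,
      _["flux"] = DataFrame::create(_["t"] = wrap(fluxT),
                                    _["flux"] = wrap(fluxQ),
                                    _["p_in"] = wrap(fluxP)),
      _["diag"] = List::create(_["final_residual"] = finalResid,
                               _["cycle_delta"] = cycleDelta,
                               _["dt_last"] = dtLast,
                               _["cg_iterations"] = (double)cgTotal));
}
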