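// D3Q19 lattice Boltzmann stepping core.
//
// Operates on "packed" arrays holding only the active (non-solid) nodes of a
// voxelized domain. Streaming uses a pull scheme through a precomputed source
// table; a source index of -1 encodes a link blocked by a solid node (or the
// domain hull on non-periodic axes) and triggers halfway bounce-back of the
// node's own post-collision population. All geometry/periodicity logic lives
// on the R side when the source table is built.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double CS2 = 1.0 / 3.0;

// BGK quadratic equilibrium, Maxwell-Boltzmann second-order expansion.
static inline void feq_bgk(double rho, double ux, double uy, double uz,
                           const int* ex, const int* ey, const int* ez,
                           const double* w, double* out) {
  const double usq = ux * ux + uy * uy + uz * uz;
  for (int i = 0; i < 19; ++i) {
    const double eu = ex[i] * ux + ey[i] * uy + ez[i] * uz;
    out[i] = w[i] * rho * (1.0 + 3.0 * eu + 4.5 * eu * eu - 1.5 * usq);
  }
}

// Incompressible variant: velocity terms scaled by the constant rho0.
static inline void feq_inc(double rho, double rho0, double ux, double uy,
                           double uz, const int* ex, const int* ey,
                           const int* ez, const double* w, double* out) {
  const double usq = ux * ux + uy * uy + uz * uz;
  for (int i = 0; i < 19; ++i) {
    const double eu = ex[i] * ux + ey[i] * uy + ez[i] * uz;
    out[i] = w[i] * (rho + rho0 * (3.0 * eu + 4.5 * eu * eu - 1.5 * usq));
  }
}

// [[Rcpp::export]]
List lbm_run_cpp(NumericMatrix f_in,        // na x 19 populations (packed)
                 IntegerMatrix src,         // na x 19 pull-source index or -1
                 IntegerVector flags,       // na: 0 fluid, 1 inlet, 2 outlet
                 IntegerMatrix evec,        // 19 x 3 lattice directions
                 NumericVector wvec,        // 19 weights
                 IntegerVector oppvec,      // 19 opposite-direction map
                 int model,                 // 0 bgk, 1 incomp, 2 reg, 3 mrt
                 double tau, double rho0,
                 NumericMatrix M, NumericMatrix Minv, NumericVector rates,
                 IntegerVector inletIdx, NumericMatrix inletU,
                 IntegerVector inletNbr,
                 IntegerVector outletIdx, IntegerVector outletNbr,
                 double outletRho,
                 NumericVector bodyForce,   // constant force density (3)
                 bool multiphase, double G, double psiRho0, bool scWeighted,
                 double psiWall,
                 int maxSteps, int checkEvery, double tol, int rampSteps,
                 bool budget) {
  const int na = f_in.nrow();
  int ex[19], ey[19], ez[19], opp[19];
  double w[19];
  for (int i = 0; i < 19; ++i) {
    ex[i] = evec(i, 0); ey[i] = evec(i, 1); ez[i] = evec(i, 2);
    w[i] = wvec[i]; opp[i] = oppvec[i];
  }

  std::vector<double> f(na * 19), fnew(na * 19);
  for (int i = 0; i < 19; ++i)
    for (int c = 0; c < na; ++c) f[(size_t)i * na + c] = f_in(c, i);

  // raw copy of the pull-source table (column-major like the population
  // storage) so the hot loops avoid Rcpp element accessors
  std::vector<int> srcv((size_t)na * 19);
  for (int i = 0; i < 19; ++i)
    for (int c = 0; c < na; ++c) srcv[(size_t)i * na + c] = src(c, i);

  const bool mrt = (model == 3);
  std::vector<double> Mm, Mi;
  if (mrt) {
    Mm.resize(361); Mi.resize(361);
    for (int r = 0; r < 19; ++r)
      for (int cc = 0; cc < 19; ++cc) {
        Mm[r * 19 + cc] = M(r, cc);
        Mi[r * 19 + cc] = Minv(r, cc);
      }
  }

  std::vector<double> rhoAll(na), psiAll, Fx, Fy, Fz;
  const bool haveBody = (bodyForce[0] != 0.0 || bodyForce[1] != 0.0 ||
                         bodyForce[2] != 0.0);
  if (multiphase) { psiAll.resize(na); Fx.resize(na); Fy.resize(na); Fz.resize(na); }

  std::vector<double> uPrev;            // residual reference (3*na)
  bool havePrev = false;
  std::vector<double> residuals;
  std::vector<double> massTr, pxTr, pyTr, pzTr;

  bool converged = false, diverged = false;
  int divergeStep = -1, divergeNode = -1;
  int stepsRun = 0;
  const double omega = 1.0 / tau;

  double fe[19], fn[19], mvec[19];

  for (int step = 0; step < maxSteps; ++step) {
    const double ramp =
        (rampSteps > 0 && step < rampSteps) ? (step + 1.0) / rampSteps : 1.0;

    // --- Shan-Chen interaction force (needs the full density field first) ---
    if (multiphase) {
      for (int c = 0; c < na; ++c) {
        double r = 0.0;
        for (int i = 0; i < 19; ++i) r += f[(size_t)i * na + c];
        rhoAll[c] = r;
        psiAll[c] = psiRho0 * (1.0 - std::exp(-r / psiRho0));
      }
      for (int c = 0; c < na; ++c) {
        double sx = 0.0, sy = 0.0, sz = 0.0;
        for (int i = 1; i < 19; ++i) {
          // neighbour at x + e_i is the pull source of the opposite direction
          const int j = srcv[(size_t)opp[i] * na + c];
          const double pj = (j >= 0) ? psiAll[j] : psiWall;
          const double wt = scWeighted ? w[i] : 1.0;
          sx += wt * pj * ex[i];
          sy += wt * pj * ey[i];
          sz += wt * pj * ez[i];
        }
        const double a = -G * psiAll[c];
        Fx[c] = a * sx; Fy[c] = a * sy; Fz[c] = a * sz;
      }
    }

    // --- collision (in place) ---
    for (int c = 0; c < na; ++c) {
      double rho = 0.0, mx = 0.0, my = 0.0, mz = 0.0;
      for (int i = 0; i < 19; ++i) {
        const double fi = f[(size_t)i * na + c];
        rho += fi; mx += fi * ex[i]; my += fi * ey[i]; mz += fi * ez[i];
      }
      if (!(rho > 0.0) || !std::isfinite(rho)) {
        diverged = true; divergeStep = step; divergeNode = c;
        break;
      }
      double fx = bodyForce[0], fy = bodyForce[1], fz = bodyForce[2];
      if (multiphase) { fx += Fx[c]; fy += Fy[c]; fz += Fz[c]; }
      const bool forced = (fx != 0.0 || fy != 0.0 || fz != 0.0);
      const double rdiv = (model == 1) ? rho0 : rho;
      const double ux = mx / rdiv, uy = my / rdiv, uz = mz / rdiv;

      if (model == 1) feq_inc(rho, rho0, ux, uy, uz, ex, ey, ez, w, fe);
      else            feq_bgk(rho, ux, uy, uz, ex, ey, ez, w, fe);

      // velocity-shift forcing as an explicit source: for BGK this equals
      // relaxing toward the equilibrium at u + tau F / rho; for the other
      // operators it injects the same momentum F per step
      double fsrc[19];
      if (forced) {
        const double sx = ux + tau * fx / rdiv, sy = uy + tau * fy / rdiv,
                     sz = uz + tau * fz / rdiv;
        if (model == 1) feq_inc(rho, rho0, sx, sy, sz, ex, ey, ez, w, fsrc);
        else            feq_bgk(rho, sx, sy, sz, ex, ey, ez, w, fsrc);
        for (int i = 0; i < 19; ++i) fsrc[i] = omega * (fsrc[i] - fe[i]);
      }

      if (model == 0 || model == 1) {
        for (int i = 0; i < 19; ++i) {
          const size_t k = (size_t)i * na + c;
          f[k] -= omega * (f[k] - fe[i]);
        }
      } else if (model == 2) {
        // regularized: project f^neq on its second moment before relaxing
        double pxx = 0, pyy = 0, pzz = 0, pxy = 0, pxz = 0, pyz = 0;
        for (int i = 0; i < 19; ++i) {
          const double q = f[(size_t)i * na + c] - fe[i];
          pxx += q * ex[i] * ex[i]; pyy += q * ey[i] * ey[i];
          pzz += q * ez[i] * ez[i]; pxy += q * ex[i] * ey[i];
          pxz += q * ex[i] * ez[i]; pyz += q * ey[i] * ez[i];
        }
        const double tr = pxx + pyy + pzz;
        for (int i = 0; i < 19; ++i) {
          const double qpp =
              ex[i] * ex[i] * pxx + ey[i] * ey[i] * pyy + ez[i] * ez[i] * pzz +
              2.0 * (ex[i] * ey[i] * pxy + ex[i] * ez[i] * pxz +
                     ey[i] * ez[i] * pyz) - CS2 * tr;
          const double freg = 4.5 * w[i] * qpp;   // w_i / (2 cs^4)
          f[(size_t)i * na + c] = fe[i] + (1.0 - omega) * freg;
        }
      } else {
        // MRT: relax each moment toward M f^eq at its own rate
        for (int r = 0; r < 19; ++r) {
          double s1 = 0.0, s2 = 0.0;
          const double* Mr = &Mm[r * 19];
          for (int i = 0; i < 19; ++i) {
            s1 += Mr[i] * f[(size_t)i * na + c];
            s2 += Mr[i] * fe[i];
          }
          mvec[r] = s1 - rates[r] * (s1 - s2);
        }
        for (int i = 0; i < 19; ++i) {
          double s = 0.0;
          for (int r = 0; r < 19; ++r) s += Mi[i * 19 + r] * mvec[r];
          f[(size_t)i * na + c] = s;
        }
      }
      if (forced)
        for (int i = 0; i < 19; ++i) f[(size_t)i * na + c] += fsrc[i];
    }
    if (diverged) break;

    // --- inlet / outlet reconstruction (equilibrium + copied non-eq) ---
    for (int k = 0; k < inletIdx.size(); ++k) {
      const int c = inletIdx[k], nb = inletNbr[k];
      double rb = 0.0, mbx = 0.0, mby = 0.0, mbz = 0.0;
      for (int i = 0; i < 19; ++i) {
        const double fi = f[(size_t)i * na + nb];
        rb += fi; mbx += fi * ex[i]; mby += fi * ey[i]; mbz += fi * ez[i];
      }
      // inlet density taken from the interior neighbour: a free local
      // density can cancel the imposed velocity (spurious zero-flow state)
      const double rho = rb;
      const double rdiv = (model == 1) ? rho0 : rb;
      const double ux = inletU(k, 0) * ramp, uy = inletU(k, 1) * ramp,
                   uz = inletU(k, 2) * ramp;
      if (model == 1) {
        feq_inc(rho, rho0, ux, uy, uz, ex, ey, ez, w, fe);
        feq_inc(rb, rho0, mbx / rdiv, mby / rdiv, mbz / rdiv, ex, ey, ez, w, fn);
      } else {
        feq_bgk(rho, ux, uy, uz, ex, ey, ez, w, fe);
        feq_bgk(rb, mbx / rdiv, mby / rdiv, mbz / rdiv, ex, ey, ez, w, fn);
      }
      for (int i = 0; i < 19; ++i)
        f[(size_t)i * na + c] = fe[i] + (f[(size_t)i * na + nb] - fn[i]);
    }
    for (int k = 0; k < outletIdx.size(); ++k) {
      const int c = outletIdx[k], nb = outletNbr[k];
      double rb = 0.0, mbx = 0.0, mby = 0.0, mbz = 0.0;
      for (int i = 0; i < 19; ++i) {
        const double fi = f[(size_t)i * na + nb];
        rb += fi; mbx += fi * ex[i]; mby += fi * ey[i]; mbz += fi * ez[i];
      }
      const double rdiv = (model == 1) ? rho0 : rb;
      const double ux = mbx / rdiv, uy = mby / rdiv, uz = mbz / rdiv;
      if (model == 1) {
        feq_inc(outletRho, rho0, ux, uy, uz, ex, ey, ez, w, fe);
        feq_inc(rb, rho0, ux, uy, uz, ex, ey, ez, w, fn);
      } else {
        feq_bgk(outletRho, ux, uy, uz, ex, ey, ez, w, fe);
        feq_bgk(rb, ux, uy, uz, ex, ey, ez, w, fn);
      }
      for (int i = 0; i < 19; ++i)
        f[(size_t)i * na + c] = fe[i] + (f[(size_t)i * na + nb] - fn[i]);
    }

    // --- streaming (pull) with halfway bounce-back on blocked links ---
    for (int i = 0; i < 19; ++i) {
      const size_t off = (size_t)i * na, offo = (size_t)opp[i] * na;
      const int* sp = &srcv[off];
      for (int c = 0; c < na; ++c) {
        const int j = sp[c];
        fnew[off + c] = (j >= 0) ? f[off + j] : f[offo + c];
      }
    }
    f.swap(fnew);
    ++stepsRun;

    if (budget) {
      double m = 0.0, px = 0.0, py = 0.0, pz = 0.0;
      for (int c = 0; c < na; ++c) {
        for (int i = 0; i < 19; ++i) {
          const double fi = f[(size_t)i * na + c];
          m += fi; px += fi * ex[i]; py += fi * ey[i]; pz += fi * ez[i];
        }
        px += 0.5 * (bodyForce[0] + (multiphase ? Fx[c] : 0.0));
        py += 0.5 * (bodyForce[1] + (multiphase ? Fy[c] : 0.0));
        pz += 0.5 * (bodyForce[2] + (multiphase ? Fz[c] : 0.0));
      }
      massTr.push_back(m); pxTr.push_back(px); pyTr.push_back(py);
      pzTr.push_back(pz);
    }

    // --- windowed velocity residual ---
    if (checkEvery > 0 && ((step + 1) % checkEvery == 0)) {
      std::vector<double> uCur(3 * (size_t)na);
      bool bad = false;
      for (int c = 0; c < na; ++c) {
        double rho = 0.0, mx = 0.0, my = 0.0, mz = 0.0;
        for (int i = 0; i < 19; ++i) {
          const double fi = f[(size_t)i * na + c];
          rho += fi; mx += fi * ex[i]; my += fi * ey[i]; mz += fi * ez[i];
        }
        if (!(rho > 0.0) || !std::isfinite(rho)) {
          diverged = true; divergeStep = step; divergeNode = c; bad = true;
          break;
        }
        const double rdiv = (model == 1) ? rho0 : rho;
        uCur[c] = mx / rdiv; uCur[na + c] = my / rdiv; uCur[2 * (size_t)na + c] = mz / rdiv;
      }
      if (bad) break;
      if (havePrev) {
        double num = 0.0, den = 0.0;
        for (size_t k = 0; k < uCur.size(); ++k) {
          const double d = uCur[k] - uPrev[k];
          num += d * d; den += uCur[k] * uCur[k];
        }
        const double res = std::sqrt(num / std::max(den, 1e-300));
        residuals.push_back(res);
        if (tol > 0.0 && res < tol && step + 1 >= rampSteps) {
          converged = true;
          uPrev = uCur;
          break;
        }
      }
      uPrev = uCur; havePrev = true;
    }
  }

  // final macroscopic fields (reported momentum includes the half-force)
  NumericVector rhoOut(na);
  NumericMatrix uOut(na, 3);
  for (int c = 0; c < na; ++c) {
    double rho = 0.0, mx = 0.0, my = 0.0, mz = 0.0;
    for (int i = 0; i < 19; ++i) {
      const double fi = f[(size_t)i * na + c];
      rho += fi; mx += fi * ex[i]; my += fi * ey[i]; mz += fi * ez[i];
    }
    if (haveBody || multiphase) {
      mx += 0.5 * (bodyForce[0] + (multiphase ? Fx[c] : 0.0));
      my += 0.5 * (bodyForce[1] + (multiphase ? Fy[c] : 0.0));
      mz += 0.5 * (bodyForce[2] + (multiphase ? Fz[c] : 0.0));
    }
    rhoOut[c] = rho;
    const double rdiv = (model == 1) ? rho0 : rho;
    uOut(c, 0) = mx / rdiv; uOut(c, 1) = my / rdiv; uOut(c, 2) = mz / rdiv;
  }
  NumericMatrix fOut(na, 19);
  for (int i = 0; i < 19; ++i)
    for (int c = 0; c < na; ++c) fOut(c, i) = f[(size_t)i * na + c];

  List out = List::create(
      _["f"] = fOut, _["rho"] = rhoOut, _["u"] = uOut,
      _["steps"] = stepsRun, _["residuals"] = wrap(residuals),
      _["converged"] = converged, _["diverged"] = diverged,
      _["diverge_step"] = divergeStep + 1, _["diverge_node"] = divergeNode + 1);
  if (budget)
    out["budget"] = DataFrame::create(_["mass"] = wrap(massTr),
                                      _["px"] = wrap(pxTr),
                                      _["py"] = wrap(pyTr),
                                      _["pz"] = wrap(pzTr));
  return out;
}
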