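// 1D pulse-wave solver for branching coronary trees.
//
// Interior nodes: MacCormack predictor (forward-space) / corrector
// (backward-space) for
//   dA/dt + dQ/dx = 0
//   dQ/dt + d/dx(alpha Q^2/A) + (A/rho) dP/dx = -Cf Q/A
// closed by the tube law P = Pext + beta(x) (sqrt(A) - sqrt(A0(x))).
//
// Boundary nodes: nonlinear characteristic couplings solved per step by
// damped Newton iteration -- prescribed inflow at the ostium, mass +
// total-pressure continuity at bifurcations, an integral pressure-loss
// element at stenosis interfaces, and implicit-Euler two-element
// Windkessel models at terminals. Characteristic invariants u +/- 4c are
// evaluated at the foot of the characteristic (linear interpolation
// within the boundary cell, old time level).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <functional>
#include <sstream>

using namespace Rcpp;

namespace {

struct Piece {
  int off;      // offset into flattened node arrays
  int n;        // node count
  double dx;    // m
};

struct Sten {
  int up, down;          // piece indices
  double Kv, Kt, Ku;     // coefficients
  double ru, Au, As, Ls; // SI
  double Qprev;          // interface flow at previous step
};

struct Outlet {
  int piece;
  double Rp, C;
  double Pold;           // Windkessel pressure at previous step
};

inline double tubeP(double A, double A0, double beta, double Pext) {
  return Pext + beta * (std::sqrt(A) - std::sqrt(A0));
}
inline double waveC(double A, double beta, double rho) {
  return std::sqrt(beta * std::sqrt(A) / (2.0 * rho));
}

// Gaussian elimination with partial pivoting; n <= 6
bool lin_solve(int n, double* Jm, double* b) {
  for (int k = 0; k < n; ++k) {
    int piv = k;
    double amax = std::fabs(Jm[k * n + k]);
    for (int i = k + 1; i < n; ++i) {
      double v = std::fabs(Jm[i * n + k]);
      if (v > amax) { amax = v; piv = i; }
    }
    if (amax < 1e-300) return false;
    if (piv != k) {
      for (int j = 0; j < n; ++j) std::swap(Jm[k * n + j], Jm[piv * n + j]);
      std::swap(b[k], b[piv]);
    }
    for (int i = k + 1; i < n; ++i) {
      double f = Jm[i * n + k] / Jm[k * n + k];
      for (int j = k; j < n; ++j) Jm[i * n + j] -= f * Jm[k * n + j];
      b[i] -= f * b[k];
    }
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = b[i];
    for (int j = i + 1; j < n; ++j) s -= Jm[i * n + j] * b[j];
    b[i] = s / Jm[i * n + i];
  }
  return true;
}

// damped Newton with numerical Jacobian on scaled unknowns
// tol is the target residual; after the iteration budget a result within
// loose_tol (still orders below discretization error) is accepted --
// extreme stenotic pressures push Pt cancellation past double precision.
bool newton_solve(int n, double* y,
                  const std::function<void(const double*, double*)>& resid,
                  int maxit, double tol, double loose_tol, std::string& err) {
  std::vector<double> r(n), rt(n), J(n * n), d(n), yt(n), col(n);
  resid(y, r.data());
  double nrm = 0; for (int i = 0; i < n; ++i) nrm = std::max(nrm, std::fabs(r[i]));
  for (int it = 0; it < maxit; ++it) {
    if (nrm < tol) return true;
    for (int j = 0; j < n; ++j) {
      double h = 1e-7 * std::max(std::fabs(y[j]), 1.0);
      for (int i = 0; i < n; ++i) yt[i] = y[i];
      yt[j] += h;
      resid(yt.data(), col.data());
      for (int i = 0; i < n; ++i) J[i * n + j] = (col[i] - r[i]) / h;
    }
    for (int i = 0; i < n; ++i) d[i] = -r[i];
    std::vector<double> Jc(J);
    if (!lin_solve(n, Jc.data(), d.data())) { err = "singular Jacobian"; return false; }
    double lam = 1.0;
    bool accepted = false;
    for (int half = 0; half < 8; ++half) {
      for (int i = 0; i < n; ++i) yt[i] = y[i] + lam * d[i];
      resid(yt.data(), rt.data());
      double nt = 0; for (int i = 0; i < n; ++i) nt = std::max(nt, std::fabs(rt[i]));
      if (nt < nrm || half == 7) {
        for (int i = 0; i < n; ++i) { y[i] = yt[i]; r[i] = rt[i]; }
        nrm = nt; accepted = true; break;
      }
      lam *= 0.5;
    }
    if (!accepted) break;
  }
  if (nrm < loose_tol) return true;
  std::ostringstream os;
  os << "residual inf-norm " << nrm << " after Newton iterations";
  err = os.str();
  return false;
}

} // namespace

// [[Rcpp::export]]
List solve_tree_cpp(List pieces_in, IntegerMatrix junctions, List stenoses_in,
                    NumericMatrix outlets_in, int inlet_piece,
                    NumericVector Qin, double rho, double mu, double alphaC,
                    double Cf, double Pext, double dt, int nsteps,
                    int max_cycles, double l2_tol, double cfl,
                    IntegerMatrix probes, int conv_probe, double P_init,
                    NumericVector Q_init, bool record_stenosis) {
  const int npc = pieces_in.size();
  std::vector<Piece> pc(npc);
  int ntot = 0;
  for (int p = 0; p < npc; ++p) {
    List pl = pieces_in[p];
    pc[p].n = as<int>(pl["n"]);
    pc[p].dx = as<double>(pl["dx"]);
    pc[p].off = ntot;
    ntot += pc[p].n;
  }
  std::vector<double> A0(ntot), beta(ntot);
  for (int p = 0; p < npc; ++p) {
    List pl = pieces_in[p];
    NumericVector a0 = pl["A0"], bt = pl["beta"];
    for (int i = 0; i < pc[p].n; ++i) {
      A0[pc[p].off + i] = a0[i];
      beta[pc[p].off + i] = bt[i];
    }
  }

  // per-node x-gradients of A0, beta and the reference wave speed c0,
  // used by the characteristic source terms (central differences inside
  // each piece, one-sided at its ends)
  std::vector<double> dA0(ntot), dbeta(ntot), c0n(ntot), dc0(ntot);
  for (int p = 0; p < npc; ++p) {
    const int o = pc[p].off, n = pc[p].n;
    for (int i = o; i < o + n; ++i)
      c0n[i] = waveC(A0[i], beta[i], rho);
    for (int i = o; i < o + n; ++i) {
      int il = std::max(i - 1, o), ir = std::min(i + 1, o + n - 1);
      double h = (ir - il) * pc[p].dx;
      dA0[i] = (A0[ir] - A0[il]) / h;
      dbeta[i] = (beta[ir] - beta[il]) / h;
      dc0[i] = (c0n[ir] - c0n[il]) / h;
    }
  }

  const int nj = junctions.nrow();
  const int nst = stenoses_in.size();
  std::vector<Sten> st(nst);
  for (int s = 0; s < nst; ++s) {
    List sl = stenoses_in[s];
    st[s].up = as<int>(sl["up"]) - 1;
    st[s].down = as<int>(sl["down"]) - 1;
    st[s].Kv = as<double>(sl["Kv"]); st[s].Kt = as<double>(sl["Kt"]);
    st[s].Ku = as<double>(sl["Ku"]); st[s].ru = as<double>(sl["ru"]);
    st[s].Au = as<double>(sl["Au"]); st[s].As = as<double>(sl["As"]);
    st[s].Ls = as<double>(sl["Ls"]);
    st[s].Qprev = 0.0;
  }
  const int nout = outlets_in.nrow();
  std::vector<Outlet> out(nout);
  for (int o = 0; o < nout; ++o) {
    out[o].piece = (int)outlets_in(o, 0) - 1;
    out[o].Rp = outlets_in(o, 1);
    out[o].C = outlets_in(o, 2);
    out[o].Pold = outlets_in(o, 3);
  }
  const int inlet = inlet_piece - 1;

  // state: initialize A from the target mean perfusion pressure and Q
  // from the steady conductance split, to shorten the startup transient
  std::vector<double> A(ntot), Q(ntot, 0.0), As_(ntot), Qs_(ntot);
  std::vector<double> Anew(ntot), Qnew(ntot);
  std::vector<double> Pn(ntot), Fn(ntot), Ps(ntot), Fs(ntot);
  for (int i = 0; i < ntot; ++i) {
    double s = std::sqrt(A0[i]) + (P_init - Pext) / beta[i];
    if (s <= 0) stop("initial pressure implies non-positive area");
    A[i] = s * s;
  }
  for (int p = 0; p < npc; ++p)
    for (int i = pc[p].off; i < pc[p].off + pc[p].n; ++i)
      Q[i] = Q_init[p];

  const int nprobe = probes.nrow();
  NumericMatrix prbP(nsteps, nprobe), prbQ(nsteps, nprobe), prbA(nsteps, nprobe);
  std::vector<int> prbIdx(nprobe);
  for (int k = 0; k < nprobe; ++k) {
    int p = probes(k, 0) - 1, node = probes(k, 1) - 1;
    if (p < 0 || p >= npc || node < 0 || node >= pc[p].n)
      stop("probe outside the grid");
    prbIdx[k] = pc[p].off + node;
  }
  NumericMatrix stQ(record_stenosis ? nsteps : 0, nst),
      stPtu(record_stenosis ? nsteps : 0, nst),
      stPtd(record_stenosis ? nsteps : 0, nst);

  std::vector<double> convPrev(nsteps, 0.0);
  std::vector<double> l2hist;
  bool converged = false;
  int cycles_run = 0;
  double deform_mean = NA_REAL;

  const double cref = waveC(A0[pc[inlet].off], beta[pc[inlet].off], rho);
  const double tolN = 1e-10;

  for (int cyc = 0; cyc < max_cycles && !converged; ++cyc) {
    double deform_sum = 0.0;
    for (int stp = 0; stp < nsteps; ++stp) {
      // pass 1: P, F, CFL
      double maxrate = 0.0;
      for (int p = 0; p < npc; ++p) {
        const int o = pc[p].off, n = pc[p].n;
        double inv_dx = 1.0 / pc[p].dx;
        for (int i = o; i < o + n; ++i) {
          double a = A[i];
          if (!(a > 0.0) || !std::isfinite(a) || !std::isfinite(Q[i])) {
            std::ostringstream os;
            os << "instability: invalid state at piece " << (p + 1)
               << ", node " << (i - o + 1) << ", cycle " << (cyc + 1)
               << ", step " << (stp + 1);
            stop(os.str());
          }
          double sq = std::sqrt(a);
          Pn[i] = Pext + beta[i] * (sq - std::sqrt(A0[i]));
          Fn[i] = alphaC * Q[i] * Q[i] / a;
          double c = std::sqrt(beta[i] * sq / (2.0 * rho));
          double rate = (std::fabs(Q[i] / a) + c) * inv_dx;
          if (rate > maxrate) maxrate = rate;
        }
      }
      if (dt * maxrate > cfl) {
        std::ostringstream os;
        if (cyc == 0 && stp == 0)
          os << "CFL violated at start: dt = " << dt
             << " s exceeds the maximum stable step " << (cfl / maxrate)
             << " s; reduce dt or coarsen the grid";
        else
          os << "CFL violated mid-run (cycle " << (cyc + 1) << ", step "
             << (stp + 1) << "): dt = " << dt << " s, stable limit "
             << (cfl / maxrate) << " s (margin "
             << (cfl / (dt * maxrate)) << "x)";
        stop(os.str());
      }
      // predictor (forward differences)
      for (int p = 0; p < npc; ++p) {
        const int o = pc[p].off, n = pc[p].n;
        const double lam = dt / pc[p].dx;
        As_[o] = A[o]; Qs_[o] = Q[o];
        As_[o + n - 1] = A[o + n - 1]; Qs_[o + n - 1] = Q[o + n - 1];
        for (int i = o + 1; i < o + n - 1; ++i) {
          As_[i] = A[i] - lam * (Q[i + 1] - Q[i]);
          Qs_[i] = Q[i] - lam * (Fn[i + 1] - Fn[i])
                   - lam * (A[i] / rho) * (Pn[i + 1] - Pn[i])
                   - dt * Cf * Q[i] / A[i];
        }
      }
      for (int i = 0; i < ntot; ++i) {
        double a = As_[i];
        if (!(a > 0.0)) a = 1e-3 * A0[i]; // guarded; corrector averages it out
        Ps[i] = Pext + beta[i] * (std::sqrt(a) - std::sqrt(A0[i]));
        Fs[i] = alphaC * Qs_[i] * Qs_[i] / a;
      }
      // corrector (backward differences)
      for (int p = 0; p < npc; ++p) {
        const int o = pc[p].off, n = pc[p].n;
        const double lam = dt / pc[p].dx;
        for (int i = o + 1; i < o + n - 1; ++i) {
          Anew[i] = 0.5 * (A[i] + As_[i]) - 0.5 * lam * (Qs_[i] - Qs_[i - 1]);
          Qnew[i] = 0.5 * (Q[i] + Qs_[i])
                    - 0.5 * lam * (Fs[i] - Fs[i - 1])
                    - 0.5 * lam * (As_[i] / rho) * (Ps[i] - Ps[i - 1])
                    - 0.5 * dt * Cf * Qs_[i] / As_[i];
        }
      }

      // characteristic invariants at the feet (old time level)
      // Invariants are taken relative to the local reference wave speed
      // c0(x) = c(A0(x)) so they transport cleanly along tapered vessels,
      // and the characteristic source terms (wall friction plus the
      // geometry terms from beta(x), A0(x)) are integrated over the step:
      //   dW+/dt = -Cf u/A - G + 4 (u+c)(c beta'/(2 beta) - c0')
      //   dW-/dt = -Cf u/A - G - 4 (u-c)(c beta'/(2 beta) - c0')
      //   G = [beta' (sqrt(A)-sqrt(A0)) - beta A0'/(2 sqrt(A0))] / rho
      auto Wsrc = [&](int i, int sgn) {
        double u = Q[i] / A[i];
        double sq = std::sqrt(A[i]);
        double c = std::sqrt(beta[i] * sq / (2.0 * rho));
        double G = (dbeta[i] * (sq - std::sqrt(A0[i])) -
                    beta[i] * dA0[i] / (2.0 * std::sqrt(A0[i]))) / rho;
        double geo = c * dbeta[i] / (2.0 * beta[i]) - dc0[i];
        return -Cf * u / A[i] - G +
               sgn * 4.0 * (u + sgn * c) * geo;
      };
      auto Wplus_end = [&](int p) {
        int e = pc[p].off + pc[p].n - 1;
        double u = Q[e] / A[e], c = waveC(A[e], beta[e], rho);
        double th = (u + c) * dt / pc[p].dx;
        th = std::min(1.0, std::max(0.0, th));
        double u2 = Q[e - 1] / A[e - 1], c2 = waveC(A[e - 1], beta[e - 1], rho);
        double w = (1.0 - th) * (u + 4.0 * (c - c0n[e])) +
                   th * (u2 + 4.0 * (c2 - c0n[e - 1]));
        return w + dt * Wsrc(e, +1);
      };
      auto Wminus_start = [&](int p) {
        int b = pc[p].off;
        double u = Q[b] / A[b], c = waveC(A[b], beta[b], rho);
        double th = (c - u) * dt / pc[p].dx;
        th = std::min(1.0, std::max(0.0, th));
        double u2 = Q[b + 1] / A[b + 1], c2 = waveC(A[b + 1], beta[b + 1], rho);
        double w = (1.0 - th) * (u - 4.0 * (c - c0n[b])) +
                   th * (u2 - 4.0 * (c2 - c0n[b + 1]));
        return w + dt * Wsrc(b, -1);
      };

      // inlet: prescribed flow, area from the backward characteristic
      {
        int b = pc[inlet].off;
        double Qt = Qin[(stp + 1) % nsteps];
        double Wm = Wminus_start(inlet);
        double a = A[b];
        double c0b = waveC(A0[b], beta[b], rho);
        for (int it = 0; it < 60; ++it) {
          double c = waveC(a, beta[b], rho);
          double f = Qt / a - 4.0 * (c - c0b) - Wm;
          double df = -Qt / (a * a) - c / a;
          double da = -f / df;
          if (da > 0.5 * a) da = 0.5 * a;
          if (da < -0.5 * a) da = -0.5 * a;
          a += da;
          if (std::fabs(da) < 1e-14 * A0[b]) break;
        }
        if (!(a > 0.0) || !std::isfinite(a))
          stop("inlet coupling failed to produce a positive area");
        Anew[b] = a; Qnew[b] = Qt;
      }

      // bifurcations: mass + total-pressure continuity + characteristics.
      // The characteristic relations determine Q(A) at each end, leaving a
      // 3-unknown Newton system (areas) with an analytic Jacobian.
      for (int j = 0; j < nj; ++j) {
        int pp = junctions(j, 0) - 1, p1 = junctions(j, 1) - 1,
            p2 = junctions(j, 2) - 1;
        int ep = pc[pp].off + pc[pp].n - 1, b1 = pc[p1].off, b2 = pc[p2].off;
        double Wp = Wplus_end(pp), W1 = Wminus_start(p1), W2 = Wminus_start(p2);
        double c0p = waveC(A0[ep], beta[ep], rho),
               c01 = waveC(A0[b1], beta[b1], rho),
               c02 = waveC(A0[b2], beta[b2], rho);
        double Aj[3] = { A[ep], A[b1], A[b2] };
        const int nd[3] = { ep, b1, b2 };
        const double c0j[3] = { c0p, c01, c02 };
        const double Wj[3] = { Wp, W1, W2 };
        double sQ = A0[ep] * 1.0;
        double Pr = rho * cref * cref;
        double uj[3], cj[3], Qj[3], Ptj[3], dQ[3], dPt[3];
        double res[3], dx3[3], J[9];
        bool ok = false;
        double nrm_last = 1e300;
        for (int it = 0; it < 80; ++it) {
          for (int q = 0; q < 3; ++q) {
            int i = nd[q];
            double sq = std::sqrt(Aj[q]);
            cj[q] = std::sqrt(beta[i] * sq / (2.0 * rho));
            double sgn = (q == 0) ? -1.0 : 1.0; // parent: u = W - 4(c-c0)
            uj[q] = Wj[q] + sgn * 4.0 * (cj[q] - c0j[q]);
            Qj[q] = Aj[q] * uj[q];
            Ptj[q] = tubeP(Aj[q], A0[i], beta[i], Pext) +
                     0.5 * rho * uj[q] * uj[q];
            dQ[q] = uj[q] + sgn * cj[q];
            dPt[q] = beta[i] / (2.0 * sq) + sgn * rho * uj[q] * cj[q] / Aj[q];
          }
          double Prs = std::max(Pr, std::fabs(Ptj[0]));
          res[0] = (Qj[0] - Qj[1] - Qj[2]) / sQ;
          res[1] = (Ptj[0] - Ptj[1]) / Prs;
          res[2] = (Ptj[0] - Ptj[2]) / Prs;
          double nrm = std::max(std::fabs(res[0]),
                                std::max(std::fabs(res[1]), std::fabs(res[2])));
          if (nrm < tolN) { ok = true; break; }
          if (it == 79) { ok = nrm < 1e-5; break; }
          nrm_last = nrm;
          J[0] = dQ[0] / sQ; J[1] = -dQ[1] / sQ; J[2] = -dQ[2] / sQ;
          J[3] = dPt[0] / Prs; J[4] = -dPt[1] / Prs; J[5] = 0.0;
          J[6] = dPt[0] / Prs; J[7] = 0.0; J[8] = -dPt[2] / Prs;
          dx3[0] = -res[0]; dx3[1] = -res[1]; dx3[2] = -res[2];
          if (!lin_solve(3, J, dx3)) break;
          double lam = 1.0;
          for (int q = 0; q < 3; ++q) {
            double lim = 0.5 * Aj[q] / std::max(std::fabs(dx3[q]), 1e-300);
            if (lim < lam) lam = lim;
          }
          for (int q = 0; q < 3; ++q) Aj[q] += lam * dx3[q];
        }
        if (!ok) {
          std::ostringstream os;
          os << "junction solve error (junction " << (j + 1) << ", cycle "
             << (cyc + 1) << ", step " << (stp + 1)
             << "): scaled residuals [" << res[0] << ", " << res[1] << ", "
             << res[2] << "]";
          stop(os.str());
        }
        Anew[ep] = Aj[0]; Qnew[ep] = Qj[0];
        Anew[b1] = Aj[1]; Qnew[b1] = Qj[1];
        Anew[b2] = Aj[2]; Qnew[b2] = Qj[2];
      }

      // stenosis interfaces: flow continuity + total-pressure jump equal
      // to the integral pressure-loss element (viscous + turbulent +
      // inertial terms); 2-unknown Newton with analytic Jacobian.
      for (int s = 0; s < nst; ++s) {
        int eu = pc[st[s].up].off + pc[st[s].up].n - 1, bd = pc[st[s].down].off;
        double Wp = Wplus_end(st[s].up), Wm = Wminus_start(st[s].down);
        double c0u = waveC(A0[eu], beta[eu], rho),
               c0d = waveC(A0[bd], beta[bd], rho);
        double kv = mu * st[s].Kv / (2.0 * M_PI * st[s].ru * st[s].ru * st[s].ru);
        double kt = rho * st[s].Kt / (2.0 * st[s].Au * st[s].Au) *
                    std::pow(st[s].Au / st[s].As - 1.0, 2);
        double ku = rho * st[s].Ku * st[s].Ls / st[s].Au;
        double Qp = st[s].Qprev;
        double sQ = A0[eu] * 1.0;
        double Pr = rho * cref * cref;
        double Au_ = A[eu], Ad_ = A[bd];
        double uu = 0, ud = 0, Qq = 0;
        double res0 = 0, res1 = 0;
        bool ok = false;
        for (int it = 0; it < 80; ++it) {
          double squ = std::sqrt(Au_), sqd = std::sqrt(Ad_);
          double cu = std::sqrt(beta[eu] * squ / (2.0 * rho));
          double cd = std::sqrt(beta[bd] * sqd / (2.0 * rho));
          uu = Wp - 4.0 * (cu - c0u);
          ud = Wm + 4.0 * (cd - c0d);
          double Qu = Au_ * uu, Qd = Ad_ * ud;
          Qq = 0.5 * (Qu + Qd);
          double Ptu = tubeP(Au_, A0[eu], beta[eu], Pext) + 0.5 * rho * uu * uu;
          double Ptd = tubeP(Ad_, A0[bd], beta[bd], Pext) + 0.5 * rho * ud * ud;
          double dPs = kv * Qq + kt * std::fabs(Qq) * Qq + ku * (Qq - Qp) / dt;
          double Prs = std::max(Pr, std::fabs(Ptu));
          res0 = (Qu - Qd) / sQ;
          res1 = (Ptu - Ptd - dPs) / Prs;
          double nrm = std::max(std::fabs(res0), std::fabs(res1));
          if (nrm < tolN) { ok = true; break; }
          if (it == 79) { ok = nrm < 1e-5; break; }
          double dQu = uu - cu, dQd = ud + cd;
          double dPtu = beta[eu] / (2.0 * squ) - rho * uu * cu / Au_;
          double dPtd = beta[bd] / (2.0 * sqd) + rho * ud * cd / Ad_;
          double ddPs = kv + 2.0 * kt * std::fabs(Qq) + ku / dt;
          double J00 = dQu / sQ, J01 = -dQd / sQ;
          double J10 = (dPtu - ddPs * 0.5 * dQu) / Prs;
          double J11 = (-dPtd - ddPs * 0.5 * dQd) / Prs;
          double det = J00 * J11 - J01 * J10;
          if (std::fabs(det) < 1e-300) break;
          double dAu = (-res0 * J11 + res1 * J01) / det;
          double dAd = (-J00 * res1 + J10 * res0) / det;
          double lam = 1.0;
          double limu = 0.5 * Au_ / std::max(std::fabs(dAu), 1e-300);
          double limd = 0.5 * Ad_ / std::max(std::fabs(dAd), 1e-300);
          if (limu < lam) lam = limu;
          if (limd < lam) lam = limd;
          Au_ += lam * dAu; Ad_ += lam * dAd;
        }
        if (!ok) {
          std::ostringstream os;
          os << "stenosis solve error (interface " << (s + 1) << ", cycle "
             << (cyc + 1) << ", step " << (stp + 1)
             << "): scaled residuals [" << res0 << ", " << res1 << "]";
          stop(os.str());
        }
        Anew[eu] = Au_; Qnew[eu] = Qq;
        Anew[bd] = Ad_; Qnew[bd] = Qq;
        if (record_stenosis) {
          double uun = Qq / Au_, udn = Qq / Ad_;
          stQ(stp, s) = Qq;
          stPtu(stp, s) = tubeP(Au_, A0[eu], beta[eu], Pext) +
                          0.5 * rho * uun * uun;
          stPtd(stp, s) = tubeP(Ad_, A0[bd], beta[bd], Pext) +
                          0.5 * rho * udn * udn;
        }
        st[s].Qprev = Qq;
      }

      // terminals: implicit-Euler Windkessel via the forward characteristic
      for (int o2 = 0; o2 < nout; ++o2) {
        Outlet& ot = out[o2];
        int e = pc[ot.piece].off + pc[ot.piece].n - 1;
        double Wp = Wplus_end(ot.piece);
        double a = A[e];
        double c0e = waveC(A0[e], beta[e], rho);
        for (int it = 0; it < 60; ++it) {
          double sq = std::sqrt(a);
          double c = std::sqrt(beta[e] * sq / (2.0 * rho));
          double u = Wp - 4.0 * (c - c0e);
          double P = Pext + beta[e] * (sq - std::sqrt(A0[e]));
          double f = (ot.C / dt) * (P - ot.Pold) - u * a + P / ot.Rp;
          double dPdA = beta[e] / (2.0 * sq);
          double df = (ot.C / dt + 1.0 / ot.Rp) * dPdA - (u - c);
          double da = -f / df;
          if (da > 0.5 * a) da = 0.5 * a;
          if (da < -0.5 * a) da = -0.5 * a;
          a += da;
          if (std::fabs(da) < 1e-14 * A0[e]) break;
        }
        if (!(a > 0.0) || !std::isfinite(a))
          stop("outlet coupling failed to produce a positive area");
        double c = waveC(a, beta[e], rho);
        Anew[e] = a;
        Qnew[e] = (Wp - 4.0 * (c - c0e)) * a;
        ot.Pold = tubeP(a, A0[e], beta[e], Pext);
      }

      // commit, record, accumulate deformation
      std::swap(A, Anew); std::swap(Q, Qnew);
      for (int k = 0; k < nprobe; ++k) {
        int i = prbIdx[k];
        prbP(stp, k) = tubeP(A[i], A0[i], beta[i], Pext);
        prbQ(stp, k) = Q[i];
        prbA(stp, k) = A[i];
      }
      for (int i = 0; i < ntot; ++i)
        deform_sum += std::fabs(A[i] - A0[i]) / A0[i];
    }
    cycles_run = cyc + 1;
    deform_mean = 100.0 * deform_sum / ((double)ntot * nsteps);
    if (cyc == 0) {
      l2hist.push_back(NA_REAL);
    } else {
      double num = 0, den = 0;
      for (int stp = 0; stp < nsteps; ++stp) {
        double a = prbP(stp, conv_probe - 1);
        double d = a - convPrev[stp];
        num += d * d; den += a * a;
      }
      double rel = std::sqrt(num / std::max(den, 1e-300));
      l2hist.push_back(rel);
      if (rel < l2_tol) converged = true;
    }
    for (int stp = 0; stp < nsteps; ++stp)
      convPrev[stp] = prbP(stp, conv_probe - 1);
  }

  NumericVector tvec(nsteps);
  for (int stp = 0; stp < nsteps; ++stp) tvec[stp] = (stp + 1) * dt;

  return List::create(
      _["t"] = tvec, _["P"] = prbP, _["Q"] = prbQ, _["A"] = prbA,
      _["cycles_run"] = cycles_run, _["l2_history"] = wrap(l2hist),
      _["converged"] = converged,
      _["mean_area_deformation_pct"] = deform_mean,
      _["sten_Q"] = stQ, _["sten_Pt_up"] = stPtu, _["sten_Pt_down"] = stPtd);
}
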