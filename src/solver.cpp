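// Closed-loop 1D-0D hemodynamics solver.
//
// 1D segments: (A, Q) system in conservative form, closed by the
// square-root tube law P = P0 + beta/A0 (sqrt(A) - sqrt(A0)) with
// beta = sqrt(pi) Eh / (1 - sigma^2).  Interior nodes advance with the
// two-step (Richtmyer) Lax-Wendroff scheme; junction, stenosis-interface,
// outlet and inlet nodes are closed with outgoing Riemann invariants
// (W+- = u +- 4c) and Newton-Raphson solves enforcing mass and total
// pressure (plus the empirical stenosis pressure-loss jump).  The 0D
// side (Windkessel capacitors, RLC body blocks, passive atrium,
// time-varying elastance ventricle with diode valves) advances with RK4
// holding the 1D boundary flows frozen over the step.
//
// All quantities here are SI.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <sstream>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Segment {
  int n;           // nodes
  double dx;       // m
  double A0;       // m^2
  double beta;     // Pa m (sqrt(pi) Eh / (1 - sigma^2))
  double P0;       // Pa
  double cc;       // c = cc * A^{1/4}
  double b3;       // beta / (3 rho A0), flux coefficient
  int off;         // offset into node arrays
  // stenosis interface (between nodes m and m+1), -1 if none
  int sten_m;
  double sten_Rv;   // Pa s / m^3
  double sten_Ksep; // Pa s^2 / m^6
  double sten_Kin;  // Pa s^2 / m^3
  double sten_Qold;
};

struct JuncEnd {
  int seg;
  int node;     // 0 or n-1
  double s;     // +1: flow into junction ('end'), -1: out ('start')
  double schar; // +1: outgoing invariant is W+ (u = W - 4c), -1: W-
};

struct Junction {
  std::vector<JuncEnd> ends;
};

struct Outlet {
  int seg;      // terminal segment, node n-1
  double R1, R2, C;  // SI
  int block;
  double Pc;    // state
  double Q1d;   // boundary flow (frozen for RK4)
};

struct Block {
  double R, L, C;
  double P, Qv; // states
};

struct Heart {
  double Emax, Emin, V0, Tvc, Tvr, Tc, Rav, Rmv, Cat;
  double Pat, Vlv; // states
  double Qav;      // frozen boundary flow
};

struct Model {
  std::vector<Segment> segs;
  std::vector<Junction> juncs;
  std::vector<Outlet> outs;
  std::vector<Block> blocks;
  Heart heart;
  double rho, KR, Tc;
  int inflow_mode; // 0 heart, 1 prescribed Q(t)
  std::vector<double> qin_t, qin_q;
  int root;        // root segment index
  double newton_tol;
  int newton_maxit;
  double t;
  std::vector<double> A, Q;      // current state
  double max_mass_residual;      // diagnostics
};

inline double pres(const Segment& s, double A) {
  return s.P0 + s.beta / s.A0 * (std::sqrt(A) - std::sqrt(s.A0));
}
inline double wavec(const Segment& s, double A) {
  return s.cc * std::sqrt(std::sqrt(A));
}

double qin_interp(const Model& m, double t) {
  const std::vector<double>& tt = m.qin_t;
  const std::vector<double>& qq = m.qin_q;
  if (t <= tt.front()) return qq.front();
  if (t >= tt.back()) return qq.back();
  size_t i = std::upper_bound(tt.begin(), tt.end(), t) - tt.begin();
  double w = (t - tt[i - 1]) / (tt[i] - tt[i - 1]);
  return qq[i - 1] + w * (qq[i] - qq[i - 1]);
}

double elastance(const Heart& h, double t) {
  double tc = t - h.Tc * std::floor(t / h.Tc);
  double e;
  if (tc < h.Tvc) e = 0.5 * (1.0 - std::cos(M_PI * tc / h.Tvc));
  else if (tc < h.Tvc + h.Tvr)
    e = 0.5 * (1.0 + std::cos(M_PI * (tc - h.Tvc) / h.Tvr));
  else e = 0.0;
  return h.Emin + (h.Emax - h.Emin) * e;
}

[[noreturn]] void instability(const char* what, int seg, int node, double t) {
  std::ostringstream ss;
  ss << "solver instability: " << what << " (segment index " << seg
     << ", node " << node << ", t = " << t << " s)";
  stop(ss.str());
}

// Riemann invariant of the outgoing family, evaluated at the foot of the
// characteristic through the boundary node (linear interpolation between
// the boundary node and its interior neighbour at the old time level).
double char_W(const Model& m, const Segment& s, int bnode, double schar,
              double dt) {
  int in = (bnode == 0) ? 1 : bnode - 1;  // interior neighbour
  // also handles interior stenosis interfaces where bnode is mid-segment
  if (schar > 0 && bnode > 0) in = bnode - 1; else if (schar < 0) in = bnode + 1;
  double Ab = m.A[s.off + bnode], Qb = m.Q[s.off + bnode];
  double Ai = m.A[s.off + in], Qi = m.Q[s.off + in];
  double ub = Qb / Ab, ui = Qi / Ai;
  double cb = wavec(s, Ab), ci = wavec(s, Ai);
  double lam = ub + schar * cb;               // outgoing speed at boundary
  double w = std::fabs(lam) * dt / s.dx;      // fraction toward interior
  if (w > 1.0) w = 1.0;
  double uf = ub + w * (ui - ub);
  double cf = cb + w * (ci - cb);
  double Af = Ab + w * (Ai - Ab);
  // friction source integrated along the characteristic:
  // d(u +- 4c)/dt = -K_R u / A
  return uf + schar * 4.0 * cf - dt * m.KR * uf / Af;
}

// dense KxK linear solve (Gaussian elimination, partial pivot)
bool lin_solve(std::vector<double>& Jm, std::vector<double>& r, int K) {
  for (int col = 0; col < K; ++col) {
    int piv = col;
    for (int i = col + 1; i < K; ++i)
      if (std::fabs(Jm[i * K + col]) > std::fabs(Jm[piv * K + col])) piv = i;
    if (std::fabs(Jm[piv * K + col]) < 1e-300) return false;
    if (piv != col) {
      for (int j = 0; j < K; ++j) std::swap(Jm[col * K + j], Jm[piv * K + j]);
      std::swap(r[col], r[piv]);
    }
    for (int i = col + 1; i < K; ++i) {
      double f = Jm[i * K + col] / Jm[col * K + col];
      for (int j = col; j < K; ++j) Jm[i * K + j] -= f * Jm[col * K + j];
      r[i] -= f * r[col];
    }
  }
  for (int i = K - 1; i >= 0; --i) {
    double sum = r[i];
    for (int j = i + 1; j < K; ++j) sum -= Jm[i * K + j] * r[j];
    r[i] = sum / Jm[i * K + i];
  }
  return true;
}

// Newton solve of a generic junction: unknowns A_k at each connected end,
// velocities from frozen outgoing invariants, equations: net mass flux
// and pairwise total-pressure equality (optionally with a stenosis
// pressure-loss jump for 2-end interfaces).
void solve_junction_core(Model& m, const std::vector<JuncEnd>& ends,
                         const std::vector<double>& W,
                         bool sten, double Rv, double Ksep, double Kin,
                         double Qold, double dt,
                         std::vector<double>& Aout,
                         std::vector<double>& Qout) {
  int K = (int)ends.size();
  std::vector<double> Ak(K), uk(K), ck(K);
  for (int k = 0; k < K; ++k)
    Ak[k] = m.A[m.segs[ends[k].seg].off + ends[k].node];
  std::vector<double> R(K), Jm(K * K);
  bool ok = false;
  for (int it = 0; it < m.newton_maxit; ++it) {
    for (int k = 0; k < K; ++k) {
      const Segment& s = m.segs[ends[k].seg];
      ck[k] = wavec(s, Ak[k]);
      uk[k] = W[k] - ends[k].schar * 4.0 * ck[k];
    }
    // residuals
    std::fill(Jm.begin(), Jm.end(), 0.0);
    R[0] = 0.0;
    for (int k = 0; k < K; ++k) R[0] += ends[k].s * Ak[k] * uk[k];
    double Pt0 = pres(m.segs[ends[0].seg], Ak[0]) +
                 0.5 * m.rho * uk[0] * uk[0];
    for (int j = 1; j < K; ++j) {
      double Ptj = pres(m.segs[ends[j].seg], Ak[j]) +
                   0.5 * m.rho * uk[j] * uk[j];
      R[j] = Pt0 - Ptj;
      if (sten) {
        // jump: Pt_upstream - Pt_downstream = dP(Q), Q = flow through
        double Qs = Ak[0] * uk[0];
        double dP = Rv * Qs + Ksep * Qs * std::fabs(Qs) +
                    Kin * (Qs - Qold) / dt;
        R[j] -= dP;
      }
    }
    double rmax = std::fabs(R[0]);
    for (int j = 1; j < K; ++j)
      rmax = std::max(rmax, std::fabs(R[j]) * 1e-6); // Pa scaled
    if (rmax < m.newton_tol) { ok = true; break; }
    // Jacobian
    std::vector<double> dudA(K), dPtdA(K);
    for (int k = 0; k < K; ++k) {
      const Segment& s = m.segs[ends[k].seg];
      dudA[k] = -ends[k].schar * ck[k] / Ak[k];
      double dPdA = m.rho * ck[k] * ck[k] / Ak[k];
      dPtdA[k] = dPdA + m.rho * uk[k] * dudA[k];
    }
    for (int k = 0; k < K; ++k)
      Jm[0 * K + k] = ends[k].s * (uk[k] + Ak[k] * dudA[k]);
    for (int j = 1; j < K; ++j) {
      Jm[j * K + 0] = dPtdA[0];
      Jm[j * K + j] -= dPtdA[j];
      if (sten) {
        double dQdA0 = uk[0] + Ak[0] * dudA[0];
        double Qs = Ak[0] * uk[0];
        double ddP = Rv + 2.0 * Ksep * std::fabs(Qs) + Kin / dt;
        Jm[j * K + 0] -= ddP * dQdA0;
      }
    }
    std::vector<double> rr(R);
    if (!lin_solve(Jm, rr, K)) break;
    for (int k = 0; k < K; ++k) {
      double An = Ak[k] - rr[k];
      if (An <= 0.2 * Ak[k]) An = 0.2 * Ak[k];  // damped positivity guard
      if (An >= 5.0 * Ak[k]) An = 5.0 * Ak[k];
      Ak[k] = An;
    }
  }
  if (!ok) {
    std::ostringstream ss;
    ss << "junction Newton did not converge (|mass residual| = "
       << std::fabs(R[0]) << " m^3/s at t = " << m.t << " s)";
    stop(ss.str());
  }
  double massres = std::fabs(R[0]);
  if (massres > m.max_mass_residual) m.max_mass_residual = massres;
  Aout.assign(Ak.begin(), Ak.end());
  Qout.resize(K);
  for (int k = 0; k < K; ++k) Qout[k] = Ak[k] * uk[k];
}

// one scalar Newton on f(A) = A u(A) - Qtarget(P(A)) for outlet / inlet
double scalar_newton(Model& m, const Segment& s, double W, double schar,
                     double (*flow)(double P, void* ctx), void* ctx,
                     double dflow_dP, double A_init) {
  double A = A_init;
  for (int it = 0; it < m.newton_maxit; ++it) {
    double c = wavec(s, A);
    double u = W - schar * 4.0 * c;
    double P = pres(s, A);
    double f = A * u - flow(P, ctx);
    if (std::fabs(f) < m.newton_tol) return A;
    double dudA = -schar * c / A;
    double dPdA = m.rho * c * c / A;
    double df = u + A * dudA - dflow_dP * dPdA;
    double An = A - f / df;
    if (An <= 0.2 * A) An = 0.2 * A;
    if (An >= 5.0 * A) An = 5.0 * A;
    A = An;
  }
  stop("boundary Newton did not converge");
}

struct OutletCtx { double Pc, R1; };
double outlet_flow(double P, void* ctx) {
  OutletCtx* oc = (OutletCtx*)ctx;
  return (P - oc->Pc) / oc->R1;
}
struct InletCtx { double Plv, Rav; bool open; };
double inlet_flow(double P, void* ctx) {
  InletCtx* ic = (InletCtx*)ctx;
  if (!ic->open) return 0.0;
  return (ic->Plv - P) / ic->Rav;
}
struct QfixCtx { double Qt; };
double fixed_flow(double, void* ctx) { return ((QfixCtx*)ctx)->Qt; }

// 0D right-hand side; y layout: [Pc (n_out), P_b Qv_b (2 per block),
// Pat, Vlv]
void rhs0d(const Model& m, double t, const std::vector<double>& y,
           std::vector<double>& dy) {
  int no = (int)m.outs.size(), nb = (int)m.blocks.size();
  std::vector<double> blk_in(nb, 0.0);
  for (int o = 0; o < no; ++o) {
    const Outlet& ot = m.outs[o];
    double Pb = y[no + 2 * ot.block];
    double q2 = (y[o] - Pb) / ot.R2;
    dy[o] = (ot.Q1d - q2) / ot.C;
    blk_in[ot.block] += q2;
  }
  double Pat = y[no + 2 * nb];
  double Vlv = y[no + 2 * nb + 1];
  double sumQv = 0.0;
  for (int b = 0; b < nb; ++b) {
    const Block& bl = m.blocks[b];
    double Pb = y[no + 2 * b], Qv = y[no + 2 * b + 1];
    dy[no + 2 * b] = (blk_in[b] - Qv) / bl.C;
    dy[no + 2 * b + 1] = (Pb - Pat - bl.R * Qv) / bl.L;
    sumQv += Qv;
  }
  if (m.inflow_mode == 0) {
    const Heart& h = m.heart;
    double Plv = elastance(h, t) * (Vlv - h.V0);
    double Qmv = Pat > Plv ? (Pat - Plv) / h.Rmv : 0.0;
    dy[no + 2 * nb] = (sumQv - Qmv) / h.Cat;
    dy[no + 2 * nb + 1] = Qmv - h.Qav;
  } else {
    // prescribed-inflow (open-loop) mode: atrium acts as a large venous
    // reservoir; ventricular volume is inert
    dy[no + 2 * nb] = sumQv / m.heart.Cat;
    dy[no + 2 * nb + 1] = 0.0;
  }
}

void gather0d(const Model& m, std::vector<double>& y) {
  int no = (int)m.outs.size(), nb = (int)m.blocks.size();
  y.resize(no + 2 * nb + 2);
  for (int o = 0; o < no; ++o) y[o] = m.outs[o].Pc;
  for (int b = 0; b < nb; ++b) {
    y[no + 2 * b] = m.blocks[b].P;
    y[no + 2 * b + 1] = m.blocks[b].Qv;
  }
  y[no + 2 * nb] = m.heart.Pat;
  y[no + 2 * nb + 1] = m.heart.Vlv;
}

void scatter0d(Model& m, const std::vector<double>& y) {
  int no = (int)m.outs.size(), nb = (int)m.blocks.size();
  for (int o = 0; o < no; ++o) m.outs[o].Pc = y[o];
  for (int b = 0; b < nb; ++b) {
    m.blocks[b].P = y[no + 2 * b];
    m.blocks[b].Qv = y[no + 2 * b + 1];
  }
  m.heart.Pat = y[no + 2 * nb];
  m.heart.Vlv = y[no + 2 * nb + 1];
}

void rk4_0d(Model& m, double dt) {
  std::vector<double> y, k1, k2, k3, k4, tmp;
  gather0d(m, y);
  size_t n = y.size();
  k1.resize(n); k2.resize(n); k3.resize(n); k4.resize(n); tmp.resize(n);
  rhs0d(m, m.t, y, k1);
  for (size_t i = 0; i < n; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
  rhs0d(m, m.t + 0.5 * dt, tmp, k2);
  for (size_t i = 0; i < n; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
  rhs0d(m, m.t + 0.5 * dt, tmp, k3);
  for (size_t i = 0; i < n; ++i) tmp[i] = y[i] + dt * k3[i];
  rhs0d(m, m.t + dt, tmp, k4);
  for (size_t i = 0; i < n; ++i)
    y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  scatter0d(m, y);
}

double stable_dt(const Model& m, double cfl) {
  double dt = 1e9;
  for (const Segment& s : m.segs) {
    for (int j = 0; j < s.n; ++j) {
      double A = m.A[s.off + j];
      double u = std::fabs(m.Q[s.off + j] / A);
      double c = wavec(s, A);
      double d = s.dx / (u + c);
      if (d < dt) dt = d;
    }
  }
  return cfl * dt;
}

// one global time step with dt = min(stable CFL limit, dt_cap);
// returns dt used
double advance(Model& m, double cfl, double dt_cap) {
  double dt = stable_dt(m, cfl);
  if (dt_cap > 0 && dt_cap < dt) dt = dt_cap;

  std::vector<double> An(m.A), Qn(m.Q);
  // interior Lax-Wendroff, segment by segment
  for (size_t si = 0; si < m.segs.size(); ++si) {
    const Segment& s = m.segs[si];
    int n = s.n, off = s.off;
    double lam = dt / s.dx;
    // half-step values at interfaces j+1/2, j = 0..n-2
    static std::vector<double> Ah, Qh;
    Ah.resize(n - 1); Qh.resize(n - 1);
    for (int j = 0; j < n - 1; ++j) {
      double A1 = m.A[off + j], A2 = m.A[off + j + 1];
      double Q1 = m.Q[off + j], Q2 = m.Q[off + j + 1];
      double F1a = Q1, F2a = Q2;
      double F1b = Q1 * Q1 / A1 + s.b3 * A1 * std::sqrt(A1);
      double F2b = Q2 * Q2 / A2 + s.b3 * A2 * std::sqrt(A2);
      double S1 = -m.KR * Q1 / A1, S2 = -m.KR * Q2 / A2;
      Ah[j] = 0.5 * (A1 + A2) - 0.5 * lam * (F2a - F1a);
      Qh[j] = 0.5 * (Q1 + Q2) - 0.5 * lam * (F2b - F1b) +
              0.25 * dt * (S1 + S2);
      if (!(Ah[j] > 0.0) || !std::isfinite(Qh[j]))
        instability("non-positive or non-finite half-step area",
                    (int)si, j, m.t);
    }
    // full step for interior nodes, skipping stenosis interface nodes
    for (int j = 1; j < n - 1; ++j) {
      if (s.sten_m >= 0 && (j == s.sten_m || j == s.sten_m + 1)) continue;
      double Fl_a = Qh[j - 1];
      double Fr_a = Qh[j];
      double Fl_b = Qh[j - 1] * Qh[j - 1] / Ah[j - 1] +
                    s.b3 * Ah[j - 1] * std::sqrt(Ah[j - 1]);
      double Fr_b = Qh[j] * Qh[j] / Ah[j] + s.b3 * Ah[j] * std::sqrt(Ah[j]);
      double Sl = -m.KR * Qh[j - 1] / Ah[j - 1];
      double Sr = -m.KR * Qh[j] / Ah[j];
      An[off + j] = m.A[off + j] - lam * (Fr_a - Fl_a);
      Qn[off + j] = m.Q[off + j] - lam * (Fr_b - Fl_b) +
                    0.5 * dt * (Sl + Sr);
      if (!(An[off + j] > 0.0) || !std::isfinite(Qn[off + j]))
        instability("non-positive area or non-finite flow", (int)si, j, m.t);
    }
  }

  // junctions
  for (const Junction& jn : m.juncs) {
    int K = (int)jn.ends.size();
    std::vector<double> W(K);
    for (int k = 0; k < K; ++k) {
      const JuncEnd& e = jn.ends[k];
      W[k] = char_W(m, m.segs[e.seg], e.node, e.schar, dt);
    }
    std::vector<double> Ak, Qk;
    solve_junction_core(m, jn.ends, W, false, 0, 0, 0, 0, dt, Ak, Qk);
    for (int k = 0; k < K; ++k) {
      const JuncEnd& e = jn.ends[k];
      An[m.segs[e.seg].off + e.node] = Ak[k];
      Qn[m.segs[e.seg].off + e.node] = Qk[k];
    }
  }

  // stenosis interfaces (internal 2-end "junctions" with a dP jump)
  for (size_t si = 0; si < m.segs.size(); ++si) {
    Segment& s = m.segs[si];
    if (s.sten_m < 0) continue;
    std::vector<JuncEnd> ends(2);
    ends[0].seg = (int)si; ends[0].node = s.sten_m;
    ends[0].s = +1; ends[0].schar = +1;
    ends[1].seg = (int)si; ends[1].node = s.sten_m + 1;
    ends[1].s = -1; ends[1].schar = -1;
    std::vector<double> W(2);
    W[0] = char_W(m, s, s.sten_m, +1.0, dt);
    W[1] = char_W(m, s, s.sten_m + 1, -1.0, dt);
    std::vector<double> Ak, Qk;
    solve_junction_core(m, ends, W, true, s.sten_Rv, s.sten_Ksep,
                        s.sten_Kin, s.sten_Qold, dt, Ak, Qk);
    An[s.off + s.sten_m] = Ak[0];
    Qn[s.off + s.sten_m] = Qk[0];
    An[s.off + s.sten_m + 1] = Ak[1];
    Qn[s.off + s.sten_m + 1] = Qk[1];
    s.sten_Qold = Qk[0];
  }

  // Windkessel outlets
  for (Outlet& o : m.outs) {
    const Segment& s = m.segs[o.seg];
    double W = char_W(m, s, s.n - 1, +1.0, dt);
    OutletCtx oc; oc.Pc = o.Pc; oc.R1 = o.R1;
    double A = scalar_newton(m, s, W, +1.0, outlet_flow, &oc,
                             1.0 / o.R1, m.A[s.off + s.n - 1]);
    double u = W - 4.0 * wavec(s, A);
    An[s.off + s.n - 1] = A;
    Qn[s.off + s.n - 1] = A * u;
    o.Q1d = A * u;
  }

  // inlet
  {
    const Segment& s = m.segs[m.root];
    double W = char_W(m, s, 0, -1.0, dt);
    double A, u;
    if (m.inflow_mode == 1) {
      QfixCtx qc; qc.Qt = qin_interp(m, m.t + dt);
      A = scalar_newton(m, s, W, -1.0, fixed_flow, &qc, 0.0, m.A[s.off]);
    } else {
      double Plv = elastance(m.heart, m.t) * (m.heart.Vlv - m.heart.V0);
      InletCtx ic; ic.Plv = Plv; ic.Rav = m.heart.Rav; ic.open = true;
      A = scalar_newton(m, s, W, -1.0, inlet_flow, &ic,
                        -1.0 / m.heart.Rav, m.A[s.off]);
      u = W + 4.0 * wavec(s, A);
      if (A * u < 0.0) { // valve closed: enforce zero flow
        QfixCtx qc; qc.Qt = 0.0;
        A = scalar_newton(m, s, W, -1.0, fixed_flow, &qc, 0.0, m.A[s.off]);
      }
    }
    u = W + 4.0 * wavec(s, A);
    An[s.off] = A;
    Qn[s.off] = A * u;
    m.heart.Qav = A * u;
  }

  // 0D advance with frozen boundary flows
  rk4_0d(m, dt);

  m.A.swap(An);
  m.Q.swap(Qn);
  m.t += dt;
  return dt;
}

Model build_model(List net, List settings) {
  Model m;
  m.rho = as<double>(settings["rho"]);
  m.KR = as<double>(settings["KR"]);
  m.Tc = as<double>(settings["Tc"]);
  m.newton_tol = as<double>(settings["newton_tol"]);
  m.newton_maxit = as<int>(settings["newton_maxit"]);
  m.inflow_mode = as<int>(settings["inflow_mode"]);
  if (m.inflow_mode == 1) {
    m.qin_t = as<std::vector<double> >(settings["qin_t"]);
    m.qin_q = as<std::vector<double> >(settings["qin_q"]);
  }
  List segs = net["segments"];
  IntegerVector n = segs["n"];
  NumericVector dx = segs["dx"], A0 = segs["A0"], beta = segs["beta"],
                P0 = segs["P0"];
  IntegerVector sten_m = segs["sten_m"];
  NumericVector sten_Rv = segs["sten_Rv"], sten_Ksep = segs["sten_Ksep"],
                sten_Kin = segs["sten_Kin"];
  int off = 0;
  for (int i = 0; i < n.size(); ++i) {
    Segment s;
    s.n = n[i]; s.dx = dx[i]; s.A0 = A0[i]; s.beta = beta[i]; s.P0 = P0[i];
    s.cc = std::sqrt(s.beta / (2.0 * m.rho * s.A0));
    s.b3 = s.beta / (3.0 * m.rho * s.A0);
    s.off = off; off += s.n;
    s.sten_m = sten_m[i];
    s.sten_Rv = sten_Rv[i]; s.sten_Ksep = sten_Ksep[i];
    s.sten_Kin = sten_Kin[i]; s.sten_Qold = 0.0;
    m.segs.push_back(s);
  }
  m.A.assign(off, 0.0);
  m.Q.assign(off, 0.0);
  for (const Segment& s : m.segs)
    for (int j = 0; j < s.n; ++j) m.A[s.off + j] = s.A0;

  List juncs = net["junctions"];
  for (int i = 0; i < juncs.size(); ++i) {
    List jl = juncs[i];
    IntegerVector si = jl["seg"];
    IntegerVector endflag = jl["end"]; // 1 = distal end, 0 = start
    Junction jn;
    for (int k = 0; k < si.size(); ++k) {
      JuncEnd e;
      e.seg = si[k];
      if (endflag[k] == 1) { e.node = m.segs[e.seg].n - 1; e.s = +1; e.schar = +1; }
      else { e.node = 0; e.s = -1; e.schar = -1; }
      jn.ends.push_back(e);
    }
    m.juncs.push_back(jn);
  }

  List outs = net["outlets"];
  IntegerVector oseg = outs["seg"], oblk = outs["block"];
  NumericVector R1 = outs["R1"], R2 = outs["R2"], C = outs["C"],
                Pc0 = outs["Pc0"];
  for (int i = 0; i < oseg.size(); ++i) {
    Outlet o;
    o.seg = oseg[i]; o.R1 = R1[i]; o.R2 = R2[i]; o.C = C[i];
    o.block = oblk[i]; o.Pc = Pc0[i]; o.Q1d = 0.0;
    m.outs.push_back(o);
  }

  List blks = net["blocks"];
  NumericVector bR = blks["R"], bL = blks["L"], bC = blks["C"],
                bP = blks["P0"];
  for (int i = 0; i < bR.size(); ++i) {
    Block b;
    b.R = bR[i]; b.L = bL[i]; b.C = bC[i]; b.P = bP[i]; b.Qv = 0.0;
    m.blocks.push_back(b);
  }

  List hh = net["heart"];
  m.heart.Emax = hh["Emax"]; m.heart.Emin = hh["Emin"];
  m.heart.V0 = hh["V0"]; m.heart.Tvc = hh["Tvc"]; m.heart.Tvr = hh["Tvr"];
  m.heart.Tc = hh["Tc"]; m.heart.Rav = hh["Rav"]; m.heart.Rmv = hh["Rmv"];
  m.heart.Cat = hh["Cat"]; m.heart.Pat = hh["Pat0"];
  m.heart.Vlv = hh["Vlv0"]; m.heart.Qav = 0.0;
  m.root = as<int>(net["root"]);
  m.t = 0.0;
  m.max_mass_residual = 0.0;
  return m;
}

} // namespace

// [[Rcpp::export(name = ".run_simulation_cpp")]]
List run_simulation_cpp(List net, List settings) {
  Model m = build_model(net, settings);
  double cfl = as<double>(settings["CFL"]);
  int max_cycles = as<int>(settings["max_cycles"]);
  double ptol = as<double>(settings["periodicity_tol"]);
  IntegerVector flag_seg = net["flag_seg"];   // segment index of outputs
  IntegerVector flag_node = net["flag_node"]; // node index of outputs
  int map_idx = as<int>(net["map_flag_idx"]); // which flagged row is MAP

  // optional waveform recording
  IntegerVector rec_seg, rec_node;
  bool record = settings.containsElementNamed("record_seg");
  if (record) {
    rec_seg = as<IntegerVector>(settings["record_seg"]);
    rec_node = as<IntegerVector>(settings["record_node"]);
  }
  std::vector<double> rec_t;
  std::vector<std::vector<double> > rec_Q, rec_P, rec_A;
  if (record) {
    rec_Q.resize(rec_seg.size());
    rec_P.resize(rec_seg.size());
    rec_A.resize(rec_seg.size());
  }

  int nf = flag_seg.size();
  std::vector<double> intQ(nf, 0.0), intP(nf, 0.0);
  std::vector<double> prevQ(nf), prevP(nf);
  std::vector<double> qbar(nf), pbar(nf), qbar_prev;
  int no = (int)m.outs.size();
  std::vector<double> int_out(no, 0.0), prev_out(no, 0.0), out_bar(no);
  double int_co = 0.0, prev_co = 0.0, co_bar = 0.0;
  std::vector<double> trace;
  int cycles = 0;
  bool converged = false;

  auto sample_flags = [&](std::vector<double>& q, std::vector<double>& p) {
    for (int i = 0; i < nf; ++i) {
      const Segment& s = m.segs[flag_seg[i]];
      double A = m.A[s.off + flag_node[i]];
      q[i] = m.Q[s.off + flag_node[i]];
      p[i] = pres(s, A);
    }
  };

  sample_flags(prevQ, prevP);
  for (int o = 0; o < no; ++o) prev_out[o] = m.outs[o].Q1d;
  prev_co = m.heart.Qav;

  // explicit user-forced time step: raise an instability error up front
  // if it violates the CFL limit instead of letting divergence propagate
  double dt_forced = -1.0;
  if (settings.containsElementNamed("dt_forced"))
    dt_forced = as<double>(settings["dt_forced"]);

  int step_guard = 0;
  const int max_steps = 200000000;
  while (cycles < max_cycles) {
    double t_end = (cycles + 1) * m.Tc;
    // step to the end of this cycle
    while (m.t < t_end - 1e-12) {
      double dt = stable_dt(m, cfl);
      if (dt_forced > 0) {
        if (dt_forced > dt) {
          std::ostringstream ss;
          ss << "instability error: forced dt " << dt_forced
             << " s violates the CFL-stable limit " << dt << " s";
          stop(ss.str());
        }
        dt = dt_forced;
      }
      if (m.t + dt > t_end) dt = t_end - m.t;
      advance(m, cfl, dt);
      if (++step_guard > max_steps) stop("step limit exceeded");
      std::vector<double> curQ(nf), curP(nf);
      sample_flags(curQ, curP);
      for (int i = 0; i < nf; ++i) {
        intQ[i] += 0.5 * (prevQ[i] + curQ[i]) * dt;
        intP[i] += 0.5 * (prevP[i] + curP[i]) * dt;
      }
      prevQ.swap(curQ); prevP.swap(curP);
      for (int o = 0; o < no; ++o) {
        int_out[o] += 0.5 * (prev_out[o] + m.outs[o].Q1d) * dt;
        prev_out[o] = m.outs[o].Q1d;
      }
      int_co += 0.5 * (prev_co + m.heart.Qav) * dt;
      prev_co = m.heart.Qav;
      if (record) {
        rec_t.push_back(m.t);
        for (int r = 0; r < rec_seg.size(); ++r) {
          const Segment& s = m.segs[rec_seg[r]];
          double A = m.A[s.off + rec_node[r]];
          rec_A[r].push_back(A);
          rec_Q[r].push_back(m.Q[s.off + rec_node[r]]);
          rec_P[r].push_back(pres(s, A));
        }
      }
    }
    // cycle averages
    for (int i = 0; i < nf; ++i) {
      qbar[i] = intQ[i] / m.Tc;
      pbar[i] = intP[i] / m.Tc;
      intQ[i] = 0.0; intP[i] = 0.0;
    }
    for (int o = 0; o < no; ++o) {
      out_bar[o] = int_out[o] / m.Tc; int_out[o] = 0.0;
    }
    co_bar = int_co / m.Tc; int_co = 0.0;
    cycles++;
    for (int i = 0; i < nf; ++i) { trace.push_back(qbar[i]); }
    for (int i = 0; i < nf; ++i) { trace.push_back(pbar[i]); }
    if (!qbar_prev.empty()) {
      double rel = 0.0;
      const double q_atol = 1.0e-6 / 60.0;  // 1 mL/min in m^3/s
      const double p_atol = 0.1 * 133.322;  // 0.1 mmHg in Pa
      for (int i = 0; i < nf; ++i) {
        rel = std::max(rel, std::fabs(qbar[i] - qbar_prev[i]) /
                              std::max(std::fabs(qbar_prev[i]), q_atol));
        rel = std::max(rel, std::fabs(pbar[i] - qbar_prev[nf + i]) /
                              std::max(std::fabs(qbar_prev[nf + i]), p_atol));
      }
      if (rel < ptol) { converged = true; break; }
    }
    qbar_prev.assign(2 * nf, 0.0);
    for (int i = 0; i < nf; ++i) qbar_prev[i] = qbar[i];
    for (int i = 0; i < nf; ++i) qbar_prev[nf + i] = pbar[i];
  }

  List res = List::create(
    _["qbar"] = NumericVector(qbar.begin(), qbar.end()),
    _["pbar"] = NumericVector(pbar.begin(), pbar.end()),
    _["map"] = pbar[map_idx],
    _["outlet_qbar"] = NumericVector(out_bar.begin(), out_bar.end()),
    _["co"] = co_bar,
    _["cycles"] = cycles,
    _["converged"] = converged,
    _["max_mass_residual"] = m.max_mass_residual,
    _["trace"] = NumericVector(trace.begin(), trace.end())
  );
  if (record) {
    List rq(rec_seg.size()), rp(rec_seg.size()), ra(rec_seg.size());
    for (int r = 0; r < rec_seg.size(); ++r) {
      rq[r] = NumericVector(rec_Q[r].begin(), rec_Q[r].end());
      rp[r] = NumericVector(rec_P[r].begin(), rec_P[r].end());
      ra[r] = NumericVector(rec_A[r].begin(), rec_A[r].end());
    }
    res["rec_t"] = NumericVector(rec_t.begin(), rec_t.end());
    res["rec_Q"] = rq;
    res["rec_P"] = rp;
    res["rec_A"] = ra;
  }
  return res;
}

// Direct access to the junction Newton solve for verification: one
// junction with given per-end tube properties and frozen invariants.
// [[Rcpp::export(name = ".solve_junction_cpp")]]
List solve_junction_cpp(NumericVector A0, NumericVector beta,
                        NumericVector W, NumericVector s_sign,
                        NumericVector s_char, NumericVector A_init,
                        double P0, double rho, double tol, int maxit) {
  Model m;
  m.rho = rho; m.newton_tol = tol; m.newton_maxit = maxit;
  m.t = 0.0; m.max_mass_residual = 0.0;
  int K = A0.size();
  std::vector<JuncEnd> ends(K);
  int off = 0;
  for (int k = 0; k < K; ++k) {
    Segment s;
    s.n = 1; s.dx = 1; s.A0 = A0[k]; s.beta = beta[k]; s.P0 = P0;
    s.cc = std::sqrt(s.beta / (2.0 * rho * s.A0));
    s.b3 = 0; s.off = off; off += 1;
    s.sten_m = -1; s.sten_Rv = 0; s.sten_Ksep = 0; s.sten_Kin = 0;
    s.sten_Qold = 0;
    m.segs.push_back(s);
    m.A.push_back(A_init[k]);
    m.Q.push_back(0.0);
    ends[k].seg = k; ends[k].node = 0;
    ends[k].s = s_sign[k]; ends[k].schar = s_char[k];
  }
  std::vector<double> Wv(W.begin(), W.end());
  std::vector<double> Ak, Qk;
  solve_junction_core(m, ends, Wv, false, 0, 0, 0, 0, 1.0, Ak, Qk);
  return List::create(
    _["A"] = NumericVector(Ak.begin(), Ak.end()),
    _["Q"] = NumericVector(Qk.begin(), Qk.end()),
    _["mass_residual"] = m.max_mass_residual
  );
}
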