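// Core dynamics of the gated recurrent network and its credit-assignment
// (accessory) companion.  All hot loops run over the active subgraph only:
// the multiplicative gate closes every recurrent unit whose feedforward
// twin is silent, so activity (and credit) is confined to units at and
// around occupied grid cells.  R drives the RNG (unif_rand), so set.seed()
// on the R side makes every simulation reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

// Von Neumann taps: centre, up, down, left, right.
static const int DR[5] = {0, -1, 1, 0, 0};
static const int DC[5] = {0, 0, 0, -1, 1};

// Piecewise activation: identity up to a knee, logarithmic beyond, so
// activity is unbounded but grows slowly (keeps fixed points stable while
// avoiding saturation on long curves).
static inline double act_sigma(double x) {
  if (x <= 0.0) return 0.0;
  if (x <= 6.0) return x;
  return std::log(1.5 * x + 1.0) + 6.0 - std::log(10.0);
}
static inline double act_sigma_prime(double x) {
  if (x <= 0.0) return 0.0;
  if (x <= 6.0) return 1.0;
  return 1.5 / (1.5 * x + 1.0);
}
// Gate applied to feedforward activity; the default form is the printed
// bump 100x/(1+(100x)^2); a monotone saturating variant is optional.
static inline double gate_fun(double x, bool mono) {
  double u = 100.0 * x;
  if (mono) return u / (1.0 + u);
  return u / (1.0 + u * u);
}
static inline double gate_fun_prime(double x, bool mono) {
  double u = 100.0 * x;
  if (mono) { double d = 1.0 + u; return 100.0 / (d * d); }
  double d = 1.0 + u * u;
  return 100.0 * (1.0 - u * u) / (d * d);
}

struct Net {
  int H, W, C, P, NG, N0, A;
  bool share;        // kernel weight sharing across grid positions
  bool lateral;      // masked 3x3 lateral kernel within recurrent input layer
  bool skip;         // dense feedback from last hidden to recurrent input layer
  bool mono;         // monotone gate variant
  int ff_drive;      // additive feedforward drive: 0 none, 1 all layers,
                     // 2 input layer only
  double damp;       // leaky update factor alpha in (0,1]; 1 = undamped
  bool excit;        // recurrent kernels clipped non-negative after updates
  int readout;       // 0 = recurrent stream (Y), 1 = feedforward stream (X)
  // 3x3 Von Neumann kernels, stored as 5 taps (corners are structurally 0):
  // shared layout (tap*C+ci)*C+co ; per-position ((p*5+tap)*C+ci)*C+co.
  std::vector<double> V1, V2, T0, T1, U1, U2, Hg;
  std::vector<double> Hx2g;   // 2 x NG   : extra e -> grid unit g   [e*NG+g]
  std::vector<double> Hg2x;   // NG x 2   : grid unit g -> extra e   [g*2+e]
  std::vector<double> Fskip;  // N0 x NG  : hidden2 unit k -> layer0 unit j [j*NG+k]
  std::vector<double> Whid;   // NG x A   : hidden2 unit k -> action a [k*A+a]
  std::vector<double> Win;    // N0 x A   : layer0 unit j -> action a  [j*A+a]
};

static inline double kv(const std::vector<double>& K, bool share, int C,
                        int p, int tap, int ci, int co) {
  return share ? K[(tap * C + ci) * C + co]
               : K[((p * 5 + tap) * C + ci) * C + co];
}
static inline std::size_t kidx(bool share, int C, int p, int tap, int ci, int co) {
  return share ? (std::size_t)(tap * C + ci) * C + co
               : ((std::size_t)(p * 5 + tap) * C + ci) * C + co;
}

// Fixed-point state for one stimulus.
struct FP {
  std::vector<double> X0, X1, X2, phi0, phi1, phi2, preX1, preX2;
  std::vector<double> Y0, Y1, Y2, Z0, Z1, Z2, preY0, preY1, preY2;
  std::vector<int> occ, cells1, cells2; // cell index lists per layer
  std::vector<int> a0, au1, au2;        // active unit lists per layer
  int tconv = 0;
  bool conv = false;
  std::vector<double> traj;   // (tconv+1) x N0 recurrent input-layer history
  std::vector<double> qtraj;  // (tconv+1) x A readout history
  int nrec = 0;
};

static Net* get_net(SEXP ptr) {
  Rcpp::XPtr<Net> xp(ptr);
  return xp.get();
}

// convolution at a target (cell, co) over a source field (grid part, C chans)
static inline double conv_at(const Net& net, const std::vector<double>& K,
                             const std::vector<double>& src, int cell, int co) {
  int r = cell / net.W, c = cell % net.W;
  double s = 0.0;
  for (int tap = 0; tap < 5; ++tap) {
    int sr = r + DR[tap], sc = c + DC[tap];
    if (sr < 0 || sr >= net.H || sc < 0 || sc >= net.W) continue;
    const double* sv = &src[(std::size_t)(sr * net.W + sc) * net.C];
    for (int ci = 0; ci < net.C; ++ci)
      s += kv(K, net.share, net.C, cell, tap, ci, co) * sv[ci];
  }
  return s;
}

// transposed convolution: credit flowing back to a source (cell, ci) from a
// target field d (grid part).  Target cell q = cell - offset(tap).
static inline double convT_at(const Net& net, const std::vector<double>& K,
                              const std::vector<double>& d, int cell, int ci) {
  int r = cell / net.W, c = cell % net.W;
  double s = 0.0;
  for (int tap = 0; tap < 5; ++tap) {
    int qr = r - DR[tap], qc = c - DC[tap];
    if (qr < 0 || qr >= net.H || qc < 0 || qc >= net.W) continue;
    int q = qr * net.W + qc;
    const double* dv = &d[(std::size_t)q * net.C];
    for (int co = 0; co < net.C; ++co)
      s += kv(K, net.share, net.C, q, tap, ci, co) * dv[co];
  }
  return s;
}

// Relax the network on one stimulus.  perturb / ybias are optional
// 3-vectors (layer, unit, h) used by the finite-difference test oracles:
// perturb adds h to a feedforward activity after the feedforward sweep,
// ybias adds a constant h to a recurrent unit's pre-activation.
static void relax(const Net& net, FP& fp,
                  const IntegerMatrix& cells, const NumericVector& values,
                  const NumericVector& extras, int max_t, double tol,
                  bool record, bool record_q,
                  const NumericVector& perturb, const NumericVector& ybias) {
  const int C = net.C, NG = net.NG, N0 = net.N0, P = net.P;
  fp.X0.assign(N0, 0.0); fp.X1.assign(NG, 0.0); fp.X2.assign(NG, 0.0);
  fp.phi0.assign(N0, 0.0); fp.phi1.assign(NG, 0.0); fp.phi2.assign(NG, 0.0);
  fp.preX1.assign(NG, 0.0); fp.preX2.assign(NG, 0.0);

  std::vector<char> occm(P, 0), m1(P, 0), m2(P, 0);
  fp.occ.clear(); fp.cells1.clear(); fp.cells2.clear();
  fp.a0.clear(); fp.au1.clear(); fp.au2.clear();

  int n = cells.nrow();
  for (int i = 0; i < n; ++i) {
    int r = cells(i, 0), c = cells(i, 1), col = cells(i, 2);
    if (r < 0 || r >= net.H || c < 0 || c >= net.W)
      stop("cell out of grid bounds");
    if (col < 0 || col >= C) stop("unknown color channel");
    int cell = r * net.W + c;
    double v = (values.size() == n) ? values[i] : 1.0;
    fp.X0[(std::size_t)cell * C + col] = v;
    if (!occm[cell]) { occm[cell] = 1; fp.occ.push_back(cell); }
  }
  fp.X0[NG] = extras[0];
  fp.X0[NG + 1] = extras[1];

  for (int cell : fp.occ) {
    int r = cell / net.W, c = cell % net.W;
    for (int tap = 0; tap < 5; ++tap) {
      int nr = r + DR[tap], nc = c + DC[tap];
      if (nr < 0 || nr >= net.H || nc < 0 || nc >= net.W) continue;
      int q = nr * net.W + nc;
      if (!m1[q]) { m1[q] = 1; fp.cells1.push_back(q); }
    }
  }
  for (int cell : fp.cells1) {
    int r = cell / net.W, c = cell % net.W;
    for (int tap = 0; tap < 5; ++tap) {
      int nr = r + DR[tap], nc = c + DC[tap];
      if (nr < 0 || nr >= net.H || nc < 0 || nc >= net.W) continue;
      int q = nr * net.W + nc;
      if (!m2[q]) { m2[q] = 1; fp.cells2.push_back(q); }
    }
  }

  // one feedforward sweep; inputs stay clamped for the whole trial
  for (int cell : fp.cells1)
    for (int co = 0; co < C; ++co) {
      double pre = conv_at(net, net.V1, fp.X0, cell, co);
      fp.preX1[(std::size_t)cell * C + co] = pre;
      fp.X1[(std::size_t)cell * C + co] = act_sigma(pre);
    }
  if (perturb.size() == 3 && (int)perturb[0] == 1)
    fp.X1[(int)perturb[1]] += perturb[2];
  for (int cell : fp.cells2)
    for (int co = 0; co < C; ++co) {
      double pre = conv_at(net, net.V2, fp.X1, cell, co);
      fp.preX2[(std::size_t)cell * C + co] = pre;
      fp.X2[(std::size_t)cell * C + co] = act_sigma(pre);
    }
  if (perturb.size() == 3 && (int)perturb[0] == 2)
    fp.X2[(int)perturb[1]] += perturb[2];

  for (int i = 0; i < n; ++i) {
    int cell = cells(i, 0) * net.W + cells(i, 1);
    int u = cell * C + cells(i, 2);
    if (fp.X0[u] > 0.0) fp.a0.push_back(u);
  }
  for (int e = 0; e < 2; ++e)
    if (fp.X0[NG + e] > 0.0) fp.a0.push_back(NG + e);
  for (int u : fp.a0) fp.phi0[u] = gate_fun(fp.X0[u], net.mono);
  for (int cell : fp.cells1)
    for (int co = 0; co < C; ++co) {
      int u = cell * C + co;
      if (fp.X1[u] > 0.0) { fp.au1.push_back(u); fp.phi1[u] = gate_fun(fp.X1[u], net.mono); }
    }
  for (int cell : fp.cells2)
    for (int co = 0; co < C; ++co) {
      int u = cell * C + co;
      if (fp.X2[u] > 0.0) { fp.au2.push_back(u); fp.phi2[u] = gate_fun(fp.X2[u], net.mono); }
    }

  // recurrent relaxation, seeded at the base representation Y(0) = X
  fp.Y0 = fp.X0; fp.Y1 = fp.X1; fp.Y2 = fp.X2;
  fp.Z0.assign(N0, 0.0); fp.Z1.assign(NG, 0.0); fp.Z2.assign(NG, 0.0);
  fp.preY0.assign(N0, 0.0); fp.preY1.assign(NG, 0.0); fp.preY2.assign(NG, 0.0);

  double yb0 = 0.0; int ybl = -1, ybu = -1;
  if (ybias.size() == 3) { ybl = (int)ybias[0]; ybu = (int)ybias[1]; yb0 = ybias[2]; }

  std::vector<double> y0n(N0, 0.0);
  fp.nrec = 0;
  if (record) {
    fp.traj.reserve((std::size_t)(max_t + 1) * N0);
    fp.traj.insert(fp.traj.end(), fp.Y0.begin(), fp.Y0.end());
    fp.nrec = 1;
  }
  if (record_q) fp.qtraj.reserve((std::size_t)(max_t + 1) * net.A);

  auto push_q = [&](void) {
    std::vector<double> q(net.A, 0.0);
    const std::vector<double>& r0 = (net.readout == 0) ? fp.Y0 : fp.X0;
    const std::vector<double>& r2 = (net.readout == 0) ? fp.Y2 : fp.X2;
    for (int j : fp.a0) {
      double v = r0[j];
      const double* wrow = &net.Win[(std::size_t)j * net.A];
      for (int a = 0; a < net.A; ++a) q[a] += wrow[a] * v;
    }
    for (int k : fp.au2) {
      double v = r2[k];
      const double* wrow = &net.Whid[(std::size_t)k * net.A];
      for (int a = 0; a < net.A; ++a) q[a] += wrow[a] * v;
    }
    fp.qtraj.insert(fp.qtraj.end(), q.begin(), q.end());
  };
  if (record_q) push_q();

  fp.conv = false; fp.tconv = 0;
  for (int t = 1; t <= max_t; ++t) {
    double dmax = 0.0;
    // layer 0 (recurrent input layer): feedback, lateral and skip input,
    // all from the previous timestep
    for (int j : fp.a0) {
      double z;
      if (j < NG) {
        int cell = j / C, ch = j % C;
        z = conv_at(net, net.U1, fp.Y1, cell, ch);
        if (net.lateral) z += conv_at(net, net.Hg, fp.Y0, cell, ch);
        z += net.Hx2g[0 * NG + j] * fp.Y0[NG] + net.Hx2g[1 * NG + j] * fp.Y0[NG + 1];
      } else {
        int e = j - NG;
        z = 0.0;
        for (int g : fp.a0) if (g < NG) z += net.Hg2x[(std::size_t)g * 2 + e] * fp.Y0[g];
      }
      if (net.skip) {
        const double* frow = &net.Fskip[(std::size_t)j * NG];
        for (int k : fp.au2) z += frow[k] * fp.Y2[k];
      }
      fp.Z0[j] = z;
      double pre = fp.phi0[j] * z;
      if (net.ff_drive != 0) pre += fp.X0[j];
      if (ybl == 0 && ybu == j) pre += yb0;
      fp.preY0[j] = pre;
      y0n[j] = (1.0 - net.damp) * fp.Y0[j] + net.damp * act_sigma(pre);
    }
    for (int j : fp.a0) {
      double d = std::fabs(y0n[j] - fp.Y0[j]);
      if (d > dmax) dmax = d;
      fp.Y0[j] = y0n[j];
    }
    // layer 1: feedback from layer 2 (previous step) + drive from layer 0
    // (current step; layers update bottom-up within a timestep)
    for (int m : fp.au1) {
      int cell = m / C, co = m % C;
      double z = conv_at(net, net.U2, fp.Y2, cell, co) +
                 conv_at(net, net.T0, fp.Y0, cell, co);
      fp.Z1[m] = z;
      double pre = fp.phi1[m] * z;
      if (net.ff_drive == 1) pre += fp.X1[m];
      if (ybl == 1 && ybu == m) pre += yb0;
      fp.preY1[m] = pre;
      double v = (1.0 - net.damp) * fp.Y1[m] + net.damp * act_sigma(pre);
      double d = std::fabs(v - fp.Y1[m]);
      if (d > dmax) dmax = d;
      fp.Y1[m] = v;
    }
    // layer 2 (top): no feedback from above
    for (int k : fp.au2) {
      int cell = k / C, co = k % C;
      double z = conv_at(net, net.T1, fp.Y1, cell, co);
      fp.Z2[k] = z;
      double pre = fp.phi2[k] * z;
      if (net.ff_drive == 1) pre += fp.X2[k];
      if (ybl == 2 && ybu == k) pre += yb0;
      fp.preY2[k] = pre;
      double v = (1.0 - net.damp) * fp.Y2[k] + net.damp * act_sigma(pre);
      double d = std::fabs(v - fp.Y2[k]);
      if (d > dmax) dmax = d;
      fp.Y2[k] = v;
    }
    if (record) {
      fp.traj.insert(fp.traj.end(), fp.Y0.begin(), fp.Y0.end());
      ++fp.nrec;
    }
    if (record_q) push_q();
    fp.tconv = t;
    if (dmax <= tol) { fp.conv = true; break; }
  }
}

static std::vector<double> compute_q(const Net& net, const FP& fp) {
  std::vector<double> q(net.A, 0.0);
  const std::vector<double>& r0 = (net.readout == 0) ? fp.Y0 : fp.X0;
  const std::vector<double>& r2 = (net.readout == 0) ? fp.Y2 : fp.X2;
  for (int j : fp.a0) {
    double v = r0[j];
    const double* wrow = &net.Win[(std::size_t)j * net.A];
    for (int a = 0; a < net.A; ++a) q[a] += wrow[a] * v;
  }
  for (int k : fp.au2) {
    double v = r2[k];
    const double* wrow = &net.Whid[(std::size_t)k * net.A];
    for (int a = 0; a < net.A; ++a) q[a] += wrow[a] * v;
  }
  return q;
}

// epsilon-greedy with Boltzmann exploration; argmax ties -> lowest index
static int pick_action(const std::vector<double>& q, double epsilon,
                       bool* explored) {
  int A = (int)q.size();
  if (explored) *explored = false;
  if (epsilon > 0.0 && unif_rand() < epsilon) {
    if (explored) *explored = true;
    double mx = q[0];
    for (int a = 1; a < A; ++a) if (q[a] > mx) mx = q[a];
    double tot = 0.0;
    std::vector<double> w(A);
    for (int a = 0; a < A; ++a) { w[a] = std::exp(q[a] - mx); tot += w[a]; }
    double u = unif_rand() * tot, cum = 0.0;
    for (int a = 0; a < A; ++a) { cum += w[a]; if (u <= cum) return a; }
    return A - 1;
  }
  int best = 0;
  for (int a = 1; a < A; ++a) if (q[a] > q[best]) best = a;
  return best;
}

// Accessory (credit-assignment) state.  S_l is the adjoint dQ_a/dy before
// the gate, acc_l = phi(X_l) * S_l is the accessory activity entering the
// four-factor update; accX_l carries credit into the feedforward stream
// through the gate derivative.
struct ACC {
  std::vector<double> S0, S1, S2, acc0, acc1, acc2;
  std::vector<double> accX0, accX1, accX2;
  std::vector<double> D0, D1, D2, DX1, DX2;
  int steps_run = 0;
  bool diverged = false;
  bool settled = false;  // accessory relaxation reached a stable state
  std::vector<double> traj; // optional acc0 history
  int nrec = 0;
};

static void accessory(const Net& net, const FP& fp, int action, int acc_steps,
                      double acc_tol, bool include_gate_path, bool record,
                      ACC& ac) {
  const int C = net.C, NG = net.NG, N0 = net.N0, A = net.A;
  ac.S0.assign(N0, 0.0); ac.S1.assign(NG, 0.0); ac.S2.assign(NG, 0.0);
  ac.acc0.assign(N0, 0.0); ac.acc1.assign(NG, 0.0); ac.acc2.assign(NG, 0.0);
  ac.D0.assign(N0, 0.0); ac.D1.assign(NG, 0.0); ac.D2.assign(NG, 0.0);
  ac.diverged = false; ac.steps_run = 0;
  std::vector<double> d0(N0, 0.0), d1(NG, 0.0), d2(NG, 0.0);
  std::vector<double> dhist;
  dhist.reserve(acc_steps);
  bool rec_readout = (net.readout == 0);
  if (record) {
    ac.traj.insert(ac.traj.end(), ac.acc0.begin(), ac.acc0.end());
    ac.nrec = 1;
  }
  // Credit flows opposite to activity (output -> top hidden -> ... ->
  // input), so the sweep updates the top layer first and reuses the fresh
  // values below it: the mirror image of the forward bottom-up sweep, with
  // the same fixed point (the simultaneous adjoint equations) but the
  // contraction properties of the forward iteration.
  for (int it = 1; it <= acc_steps; ++it) {
    double dmax = 0.0, amax = 0.0;
    for (int k : fp.au2) {
      int cell = k / C, co = k % C;
      double s = rec_readout ? net.Whid[(std::size_t)k * A + action] : 0.0;
      s += convT_at(net, net.U2, d1, cell, co);
      if (net.skip)
        for (int j : fp.a0) s += net.Fskip[(std::size_t)j * NG + k] * d0[j];
      ac.S2[k] = s;
      double v = (1.0 - net.damp) * ac.acc2[k] + net.damp * fp.phi2[k] * s;
      double d = std::fabs(v - ac.acc2[k]);
      if (d > dmax) dmax = d;
      ac.acc2[k] = v;
      d2[k] = act_sigma_prime(fp.preY2[k]) * v;
      if (std::fabs(v) > amax) amax = std::fabs(v);
    }
    for (int m : fp.au1) {
      int cell = m / C, co = m % C;
      double s = convT_at(net, net.U1, d0, cell, co) +
                 convT_at(net, net.T1, d2, cell, co);
      ac.S1[m] = s;
      double v = (1.0 - net.damp) * ac.acc1[m] + net.damp * fp.phi1[m] * s;
      double d = std::fabs(v - ac.acc1[m]);
      if (d > dmax) dmax = d;
      ac.acc1[m] = v;
      d1[m] = act_sigma_prime(fp.preY1[m]) * v;
      if (std::fabs(v) > amax) amax = std::fabs(v);
    }
    for (int j : fp.a0) {
      double s = rec_readout ? net.Win[(std::size_t)j * A + action] : 0.0;
      if (j < NG) {
        int cell = j / C, ch = j % C;
        if (net.lateral) s += convT_at(net, net.Hg, d0, cell, ch);
        s += net.Hg2x[(std::size_t)j * 2 + 0] * d0[NG] +
             net.Hg2x[(std::size_t)j * 2 + 1] * d0[NG + 1];
        s += convT_at(net, net.T0, d1, cell, ch);
      } else {
        int e = j - NG;
        for (int g : fp.a0) if (g < NG) s += net.Hx2g[(std::size_t)e * NG + g] * d0[g];
      }
      ac.S0[j] = s;
      double v = (1.0 - net.damp) * ac.acc0[j] + net.damp * fp.phi0[j] * s;
      double d = std::fabs(v - ac.acc0[j]);
      if (d > dmax) dmax = d;
      ac.acc0[j] = v;
      if (std::fabs(v) > amax) amax = std::fabs(v);
    }
    for (int j : fp.a0) d0[j] = act_sigma_prime(fp.preY0[j]) * ac.acc0[j];
    ac.steps_run = it;
    if (record) {
      ac.traj.insert(ac.traj.end(), ac.acc0.begin(), ac.acc0.end());
      ++ac.nrec;
    }
    if (amax > 1e6) { ac.diverged = true; break; }
    dhist.push_back(dmax);
    if (dmax <= acc_tol) { ac.settled = true; break; }
  }
  // A truncated relaxation still approximates the fixed-point credit as
  // long as the iteration is contracting; an expanding iteration means the
  // linearized dynamics are unstable and the credit values are meaningless.
  if (!ac.settled && !ac.diverged) {
    int nsteps = (int)dhist.size();
    if (nsteps >= 10) {
      double late = 0.0, early = 0.0;
      for (int i = nsteps - 5; i < nsteps; ++i) late += dhist[i];
      for (int i = nsteps - 10; i < nsteps - 5; ++i) early += dhist[i];
      ac.settled = (late < early) || late <= 5.0 * std::max(acc_tol, 1e-5);
    } else {
      ac.settled = true;
    }
  }
  for (int j : fp.a0) ac.D0[j] = act_sigma_prime(fp.preY0[j]) * ac.acc0[j];
  for (int m : fp.au1) ac.D1[m] = act_sigma_prime(fp.preY1[m]) * ac.acc1[m];
  for (int k : fp.au2) ac.D2[k] = act_sigma_prime(fp.preY2[k]) * ac.acc2[k];

  // feedforward stream: credit reaches X through the gate derivative, then
  // descends the feedforward hierarchy (one sweep; it is a DAG)
  ac.accX0.assign(N0, 0.0); ac.accX1.assign(NG, 0.0); ac.accX2.assign(NG, 0.0);
  ac.DX1.assign(NG, 0.0); ac.DX2.assign(NG, 0.0);
  bool ff_readout = (net.readout == 1);
  double drv1 = (net.ff_drive == 1) ? 1.0 : 0.0;
  double drv0 = (net.ff_drive != 0) ? 1.0 : 0.0;
  for (int k : fp.au2) {
    double g = 0.0;
    if (include_gate_path)
      g = (gate_fun_prime(fp.X2[k], net.mono) * fp.Z2[k] + drv1) *
          act_sigma_prime(fp.preY2[k]) * ac.S2[k];
    if (ff_readout) g += net.Whid[(std::size_t)k * A + action];
    ac.accX2[k] = g;
    ac.DX2[k] = act_sigma_prime(fp.preX2[k]) * ac.accX2[k];
  }
  for (int m : fp.au1) {
    int cell = m / C, ci = m % C;
    double g = 0.0;
    if (include_gate_path)
      g = (gate_fun_prime(fp.X1[m], net.mono) * fp.Z1[m] + drv1) *
          act_sigma_prime(fp.preY1[m]) * ac.S1[m];
    g += convT_at(net, net.V2, ac.DX2, cell, ci);
    ac.accX1[m] = g;
    ac.DX1[m] = act_sigma_prime(fp.preX1[m]) * ac.accX1[m];
  }
  for (int j : fp.a0) {
    double g = 0.0;
    if (include_gate_path)
      g = (gate_fun_prime(fp.X0[j], net.mono) * fp.Z0[j] + drv0) *
          act_sigma_prime(fp.preY0[j]) * ac.S0[j];
    if (j < NG) g += convT_at(net, net.V1, ac.DX1, j / C, j % C);
    if (ff_readout) g += net.Win[(std::size_t)j * A + action];
    ac.accX0[j] = g;
  }
}

// Apply the four-factor update (or collect exact dQ_a/dw gradients when
// grads != nullptr).  Every term is delta * pre activity * postsynaptic
// accessory activity * sigma'(postsynaptic pre-activation); for shared
// kernels the per-position contributions sum into the shared tap.
struct Grads {
  std::vector<double> V1, V2, T0, T1, U1, U2, Hg, Hx2g, Hg2x, Fskip, Whid, Win;
};

static void update_or_grads(Net& net, const FP& fp, const ACC& ac, int action,
                            double f, Grads* grads) {
  const int C = net.C, NG = net.NG, N0 = net.N0, A = net.A;
  if (grads) {
    grads->V1.assign(net.V1.size(), 0.0); grads->V2.assign(net.V2.size(), 0.0);
    grads->T0.assign(net.T0.size(), 0.0); grads->T1.assign(net.T1.size(), 0.0);
    grads->U1.assign(net.U1.size(), 0.0); grads->U2.assign(net.U2.size(), 0.0);
    grads->Hg.assign(net.Hg.size(), 0.0);
    grads->Hx2g.assign(net.Hx2g.size(), 0.0);
    grads->Hg2x.assign(net.Hg2x.size(), 0.0);
    grads->Fskip.assign(net.Fskip.size(), 0.0);
    grads->Whid.assign(net.Whid.size(), 0.0);
    grads->Win.assign(net.Win.size(), 0.0);
    f = 1.0;
  }
  const std::vector<double>& r0 = (net.readout == 0) ? fp.Y0 : fp.X0;
  const std::vector<double>& r2 = (net.readout == 0) ? fp.Y2 : fp.X2;
  // readout rows of the chosen action (output accessory unit = 1, linear)
  for (int j : fp.a0) {
    double g = f * r0[j];
    if (grads) grads->Win[(std::size_t)j * A + action] += g;
    else net.Win[(std::size_t)j * A + action] += g;
  }
  for (int k : fp.au2) {
    double g = f * r2[k];
    if (grads) grads->Whid[(std::size_t)k * A + action] += g;
    else net.Whid[(std::size_t)k * A + action] += g;
  }
  // dense skip feedback and extra-unit blocks
  if (net.skip) {
    for (int j : fp.a0) {
      double c1 = f * ac.D0[j];
      if (c1 == 0.0) continue;
      double* row = grads ? &grads->Fskip[(std::size_t)j * NG]
                          : &net.Fskip[(std::size_t)j * NG];
      for (int k : fp.au2) row[k] += c1 * fp.Y2[k];
    }
  }
  for (int e = 0; e < 2; ++e) {
    double ye = fp.Y0[NG + e];
    if (ye != 0.0) {
      for (int j : fp.a0) {
        if (j >= NG) continue;
        double g = f * ye * ac.D0[j];
        if (grads) grads->Hx2g[(std::size_t)e * NG + j] += g;
        else net.Hx2g[(std::size_t)e * NG + j] += g;
      }
    }
    double de = ac.D0[NG + e];
    if (de != 0.0) {
      for (int g0 : fp.a0) {
        if (g0 >= NG) continue;
        double g = f * fp.Y0[g0] * de;
        if (grads) grads->Hg2x[(std::size_t)g0 * 2 + e] += g;
        else net.Hg2x[(std::size_t)g0 * 2 + e] += g;
      }
    }
  }
  // kernel families: target loop x taps x source channels
  auto kern_upd = [&](std::vector<double>& K, std::vector<double>* GK,
                      const std::vector<int>& targets,
                      const std::vector<double>& D,
                      const std::vector<double>& src) {
    std::vector<double>& out = GK ? *GK : K;
    for (int u : targets) {
      double du = D[u];
      if (du == 0.0) continue;
      int cell = u / C, co = u % C;
      int r = cell / net.W, c = cell % net.W;
      double fd = f * du;
      for (int tap = 0; tap < 5; ++tap) {
        int sr = r + DR[tap], sc = c + DC[tap];
        if (sr < 0 || sr >= net.H || sc < 0 || sc >= net.W) continue;
        const double* sv = &src[(std::size_t)(sr * net.W + sc) * C];
        for (int ci = 0; ci < C; ++ci)
          out[kidx(net.share, C, cell, tap, ci, co)] += fd * sv[ci];
      }
    }
  };
  std::vector<int> a0grid;
  for (int j : fp.a0) if (j < NG) a0grid.push_back(j);
  kern_upd(net.U1, grads ? &grads->U1 : nullptr, a0grid, ac.D0, fp.Y1);
  if (net.lateral)
    kern_upd(net.Hg, grads ? &grads->Hg : nullptr, a0grid, ac.D0, fp.Y0);
  kern_upd(net.T0, grads ? &grads->T0 : nullptr, fp.au1, ac.D1, fp.Y0);
  kern_upd(net.U2, grads ? &grads->U2 : nullptr, fp.au1, ac.D1, fp.Y2);
  kern_upd(net.T1, grads ? &grads->T1 : nullptr, fp.au2, ac.D2, fp.Y1);
  kern_upd(net.V1, grads ? &grads->V1 : nullptr, fp.au1, ac.DX1, fp.X0);
  kern_upd(net.V2, grads ? &grads->V2 : nullptr, fp.au2, ac.DX2, fp.X1);
}

// ---------------------------------------------------------------- interface

static std::vector<double> as_vec(SEXP s, std::size_t len, const char* nm) {
  NumericVector v(s);
  if ((std::size_t)v.size() != len)
    stop("weight tensor '%s' has length %d, expected %d", nm, (int)v.size(),
         (int)len);
  return std::vector<double>(v.begin(), v.end());
}

// [[Rcpp::export]]
SEXP cpp_net_create(List cfg, List w) {
  Net* net = new Net();
  net->H = as<int>(cfg["height"]); net->W = as<int>(cfg["width"]);
  net->C = as<int>(cfg["n_colors"]);
  net->P = net->H * net->W;
  net->NG = net->P * net->C;
  net->N0 = net->NG + 2;
  net->A = net->P + 2;
  net->share = as<bool>(cfg["weight_sharing"]);
  net->lateral = as<bool>(cfg["grid_lateral"]);
  net->skip = as<bool>(cfg["dense_skip_feedback"]);
  net->mono = as<bool>(cfg["monotone_gate"]);
  {
    std::string fd = as<std::string>(cfg["feedforward_drive"]);
    net->ff_drive = (fd == "none") ? 0 : (fd == "input") ? 2 : 1;
  }
  net->damp = as<double>(cfg["relax_damping"]);
  if (net->damp <= 0.0 || net->damp > 1.0) stop("relax_damping must be in (0,1]");
  net->excit = as<bool>(cfg["excitatory_recurrent"]);
  std::string rs = as<std::string>(cfg["readout_stream"]);
  net->readout = (rs == "feedforward") ? 1 : 0;
  std::size_t klen = net->share ? (std::size_t)5 * net->C * net->C
                                : (std::size_t)net->P * 5 * net->C * net->C;
  net->V1 = as_vec(w["V1"], klen, "V1"); net->V2 = as_vec(w["V2"], klen, "V2");
  net->T0 = as_vec(w["T0"], klen, "T0"); net->T1 = as_vec(w["T1"], klen, "T1");
  net->U1 = as_vec(w["U1"], klen, "U1"); net->U2 = as_vec(w["U2"], klen, "U2");
  net->Hg = as_vec(w["Hg"], klen, "Hg");
  net->Hx2g = as_vec(w["Hx2g"], (std::size_t)2 * net->NG, "Hx2g");
  net->Hg2x = as_vec(w["Hg2x"], (std::size_t)net->NG * 2, "Hg2x");
  net->Fskip = as_vec(w["Fskip"], (std::size_t)net->N0 * net->NG, "Fskip");
  net->Whid = as_vec(w["Whid"], (std::size_t)net->NG * net->A, "Whid");
  net->Win = as_vec(w["Win"], (std::size_t)net->N0 * net->A, "Win");
  Rcpp::XPtr<Net> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_net_weights(SEXP ptr) {
  Net* net = get_net(ptr);
  return List::create(
      _["V1"] = NumericVector(net->V1.begin(), net->V1.end()),
      _["V2"] = NumericVector(net->V2.begin(), net->V2.end()),
      _["T0"] = NumericVector(net->T0.begin(), net->T0.end()),
      _["T1"] = NumericVector(net->T1.begin(), net->T1.end()),
      _["U1"] = NumericVector(net->U1.begin(), net->U1.end()),
      _["U2"] = NumericVector(net->U2.begin(), net->U2.end()),
      _["Hg"] = NumericVector(net->Hg.begin(), net->Hg.end()),
      _["Hx2g"] = NumericVector(net->Hx2g.begin(), net->Hx2g.end()),
      _["Hg2x"] = NumericVector(net->Hg2x.begin(), net->Hg2x.end()),
      _["Fskip"] = NumericVector(net->Fskip.begin(), net->Fskip.end()),
      _["Whid"] = NumericVector(net->Whid.begin(), net->Whid.end()),
      _["Win"] = NumericVector(net->Win.begin(), net->Win.end()));
}

// [[Rcpp::export]]
void cpp_net_set_weights(SEXP ptr, List w) {
  Net* net = get_net(ptr);
  std::size_t klen = net->V1.size();
  net->V1 = as_vec(w["V1"], klen, "V1"); net->V2 = as_vec(w["V2"], klen, "V2");
  net->T0 = as_vec(w["T0"], klen, "T0"); net->T1 = as_vec(w["T1"], klen, "T1");
  net->U1 = as_vec(w["U1"], klen, "U1"); net->U2 = as_vec(w["U2"], klen, "U2");
  net->Hg = as_vec(w["Hg"], klen, "Hg");
  net->Hx2g = as_vec(w["Hx2g"], net->Hx2g.size(), "Hx2g");
  net->Hg2x = as_vec(w["Hg2x"], net->Hg2x.size(), "Hg2x");
  net->Fskip = as_vec(w["Fskip"], net->Fskip.size(), "Fskip");
  net->Whid = as_vec(w["Whid"], net->Whid.size(), "Whid");
  net->Win = as_vec(w["Win"], net->Win.size(), "Win");
}

static List fp_to_list(const Net& net, const FP& fp, bool full) {
  std::vector<double> q = compute_q(net, fp);
  List out = List::create(
      _["q"] = NumericVector(q.begin(), q.end()),
      _["t_converged"] = fp.tconv, _["converged"] = fp.conv);
  if (full) {
    out["X0"] = NumericVector(fp.X0.begin(), fp.X0.end());
    out["X1"] = NumericVector(fp.X1.begin(), fp.X1.end());
    out["X2"] = NumericVector(fp.X2.begin(), fp.X2.end());
    out["Y0"] = NumericVector(fp.Y0.begin(), fp.Y0.end());
    out["Y1"] = NumericVector(fp.Y1.begin(), fp.Y1.end());
    out["Y2"] = NumericVector(fp.Y2.begin(), fp.Y2.end());
    out["preY0"] = NumericVector(fp.preY0.begin(), fp.preY0.end());
    out["preY1"] = NumericVector(fp.preY1.begin(), fp.preY1.end());
    out["preY2"] = NumericVector(fp.preY2.begin(), fp.preY2.end());
  }
  if (fp.nrec > 0) {
    NumericMatrix tr(fp.nrec, net.N0);
    for (int t = 0; t < fp.nrec; ++t)
      for (int j = 0; j < net.N0; ++j)
        tr(t, j) = fp.traj[(std::size_t)t * net.N0 + j];
    out["traj"] = tr;
  }
  if (!fp.qtraj.empty()) {
    int nt = (int)(fp.qtraj.size() / net.A);
    NumericMatrix qt(nt, net.A);
    for (int t = 0; t < nt; ++t)
      for (int a = 0; a < net.A; ++a)
        qt(t, a) = fp.qtraj[(std::size_t)t * net.A + a];
    out["q_traj"] = qt;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_relax(SEXP ptr, IntegerMatrix cells, NumericVector values,
               NumericVector extras, int max_t, double tol, bool record_traj,
               bool record_q, bool full, NumericVector perturb,
               NumericVector ybias) {
  Net* net = get_net(ptr);
  FP fp;
  relax(*net, fp, cells, values, extras, max_t, tol, record_traj, record_q,
        perturb, ybias);
  return fp_to_list(*net, fp, full);
}

// [[Rcpp::export]]
List cpp_accessory(SEXP ptr, IntegerMatrix cells, NumericVector values,
                   NumericVector extras, int action0, int max_t, double tol,
                   int acc_steps, double acc_tol, bool include_gate_path,
                   bool record) {
  Net* net = get_net(ptr);
  FP fp;
  relax(*net, fp, cells, values, extras, max_t, tol, false, false,
        NumericVector(0), NumericVector(0));
  ACC ac;
  accessory(*net, fp, action0, acc_steps, acc_tol, include_gate_path, record,
            ac);
  List out = List::create(
      _["acc0"] = NumericVector(ac.acc0.begin(), ac.acc0.end()),
      _["acc1"] = NumericVector(ac.acc1.begin(), ac.acc1.end()),
      _["acc2"] = NumericVector(ac.acc2.begin(), ac.acc2.end()),
      _["S0"] = NumericVector(ac.S0.begin(), ac.S0.end()),
      _["S1"] = NumericVector(ac.S1.begin(), ac.S1.end()),
      _["S2"] = NumericVector(ac.S2.begin(), ac.S2.end()),
      _["accX0"] = NumericVector(ac.accX0.begin(), ac.accX0.end()),
      _["accX1"] = NumericVector(ac.accX1.begin(), ac.accX1.end()),
      _["accX2"] = NumericVector(ac.accX2.begin(), ac.accX2.end()),
      _["n_steps"] = ac.steps_run, _["diverged"] = ac.diverged,
      _["settled"] = ac.settled,
      _["t_converged"] = fp.tconv, _["converged"] = fp.conv);
  if (ac.nrec > 0) {
    NumericMatrix tr(ac.nrec, net->N0);
    for (int t = 0; t < ac.nrec; ++t)
      for (int j = 0; j < net->N0; ++j)
        tr(t, j) = ac.traj[(std::size_t)t * net->N0 + j];
    out["acc_traj"] = tr;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_gradients(SEXP ptr, IntegerMatrix cells, NumericVector values,
                   NumericVector extras, int action0, int max_t, double tol,
                   int acc_steps, double acc_tol, bool include_gate_path) {
  Net* net = get_net(ptr);
  FP fp;
  relax(*net, fp, cells, values, extras, max_t, tol, false, false,
        NumericVector(0), NumericVector(0));
  ACC ac;
  accessory(*net, fp, action0, acc_steps, acc_tol, include_gate_path, false,
            ac);
  Grads gr;
  update_or_grads(*net, fp, ac, action0, 1.0, &gr);
  return List::create(
      _["V1"] = NumericVector(gr.V1.begin(), gr.V1.end()),
      _["V2"] = NumericVector(gr.V2.begin(), gr.V2.end()),
      _["T0"] = NumericVector(gr.T0.begin(), gr.T0.end()),
      _["T1"] = NumericVector(gr.T1.begin(), gr.T1.end()),
      _["U1"] = NumericVector(gr.U1.begin(), gr.U1.end()),
      _["U2"] = NumericVector(gr.U2.begin(), gr.U2.end()),
      _["Hg"] = NumericVector(gr.Hg.begin(), gr.Hg.end()),
      _["Hx2g"] = NumericVector(gr.Hx2g.begin(), gr.Hx2g.end()),
      _["Hg2x"] = NumericVector(gr.Hg2x.begin(), gr.Hg2x.end()),
      _["Fskip"] = NumericVector(gr.Fskip.begin(), gr.Fskip.end()),
      _["Whid"] = NumericVector(gr.Whid.begin(), gr.Whid.end()),
      _["Win"] = NumericVector(gr.Win.begin(), gr.Win.end()),
      _["diverged"] = ac.diverged);
}

// [[Rcpp::export]]
List cpp_trial(SEXP ptr, IntegerMatrix cells, NumericVector values,
               NumericVector extras, int correct0, double epsilon, bool learn,
               double lr, int acc_steps, double acc_tol,
               bool include_gate_path, int max_t, double tol,
               bool record_traj) {
  Net* net = get_net(ptr);
  FP fp;
  relax(*net, fp, cells, values, extras, max_t, tol, record_traj, false,
        NumericVector(0), NumericVector(0));
  std::vector<double> q = compute_q(*net, fp);
  bool explored = false;
  int action = pick_action(q, epsilon, &explored);
  double qa = q[action];
  double r = (action == correct0) ? 1.0 : 0.0;
  double delta = r - qa;
  bool skipped = false;
  if (learn) {
    // Updates proceed from the relaxation-capped state even when the cap
    // was hit (the action is selected there too).  Plasticity is withheld
    // only when the credit signal is meaningless — the accessory iteration
    // expanded instead of contracting.  The reward-prediction error is
    // clamped to the reward scale so that a transient mis-estimated Q-value
    // yields a bounded corrective update rather than a destructive one
    // (skipping such trials instead would freeze the network in any state
    // whose chosen Q-value is far off, with no way back).
    double delta_eff = std::max(-2.0, std::min(2.0, delta));
    if (!std::isfinite(delta)) {
      skipped = true;
    } else {
      ACC ac;
      accessory(*net, fp, action, acc_steps, acc_tol, include_gate_path,
                false, ac);
      if (ac.diverged || !ac.settled) {
        skipped = true;
      } else {
        update_or_grads(*net, fp, ac, action, lr * delta_eff, nullptr);
        if (net->excit) {
          // recurrent coupling stays excitatory: projection keeps the
          // response modulation facilitatory (suppression below the base
          // representation is not available); competition lives in the
          // signed readout weights
          auto clip0 = [](std::vector<double>& K) {
            for (double& v : K) if (v < 0.0) v = 0.0;
          };
          clip0(net->Hg); clip0(net->Hx2g); clip0(net->Hg2x);
          clip0(net->T0); clip0(net->T1); clip0(net->U1); clip0(net->U2);
        }
      }
    }
  }
  List out = List::create(
      _["action"] = action, _["q_a"] = qa, _["reward"] = r,
      _["delta"] = delta, _["correct"] = (action == correct0),
      _["explored"] = explored, _["t_converged"] = fp.tconv,
      _["converged"] = fp.conv, _["update_skipped"] = skipped);
  if (fp.nrec > 0) {
    NumericMatrix tr(fp.nrec, net->N0);
    for (int t = 0; t < fp.nrec; ++t)
      for (int j = 0; j < net->N0; ++j)
        tr(t, j) = fp.traj[(std::size_t)t * net->N0 + j];
    out["traj"] = tr;
  }
  return out;
}

// Greedy evaluation of a batch of stimuli with frozen weights (test phases,
// generalization probes, timestep scans).  Each stimulus is a list with
// elements cells, values, extras, correct (0-based action).
// [[Rcpp::export]]
List cpp_batch_greedy(SEXP ptr, List stims, int max_t, double tol) {
  Net* net = get_net(ptr);
  int n = stims.size();
  IntegerVector actions(n), tconv(n);
  NumericVector qa(n);
  LogicalVector correct(n), conv(n);
  for (int i = 0; i < n; ++i) {
    List s = stims[i];
    IntegerMatrix cells = s["cells"];
    NumericVector values = s["values"];
    NumericVector extras = s["extras"];
    int corr = as<int>(s["correct"]);
    FP fp;
    relax(*net, fp, cells, values, extras, max_t, tol, false, false,
          NumericVector(0), NumericVector(0));
    std::vector<double> q = compute_q(*net, fp);
    int a = pick_action(q, 0.0, nullptr);
    actions[i] = a;
    qa[i] = q[a];
    correct[i] = (a == corr);
    tconv[i] = fp.tconv;
    conv[i] = fp.conv;
  }
  return List::create(_["action"] = actions, _["q_a"] = qa,
                      _["correct"] = correct, _["t_converged"] = tconv,
                      _["converged"] = conv);
}
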