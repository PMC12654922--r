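// Compiled time-stepping loop for the hybrid particle/field model.
// Mirrors the R reference implementation (deterministic_drift,
// sample_fluctuations, selm_step) operation-for-operation, drawing its
// noise from R's RNG in the same canonical block order, so a run with a
// given seed reproduces the R-level stepper.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  int nx, ny;
  double dx, dV, Lx, Ly;
  // physical params
  double kB, c0, gamma, gamma_p, kPI, kCI, kCC, k0, CP, CC, CI, theta0;
  // active (evolved) components
  bool evX, evQ, evT, evC;
  // potential: 0 none, 1 harmonic, 2 kernel coupling, 3 well lattice
  int pot_type;
  double pk, pcx, pcy;                    // harmonic k, center
  double k1, sigma0, rcut, psign;         // kernel coupling
  double c2, sigma0w;                     // wells
  std::vector<double> wx, wy;             // well centers
  bool has_ifk;                           // interface kernel present
  double ifk_s0, ifk_rcut;
  std::vector<double> bath;               // ambient temperature field
  bool noise;
  int id(int i, int j) const { return i + nx * j; }
};

struct State {
  bool hasX, hasQ, hasT, hasC;
  double X0, X1, thP, thI;
  std::vector<double> q, thC;
};

struct Fields {  // scratch face/cell arrays
  std::vector<double> fx, fy, gx, gy, c1, c2;
};

inline double wrapc(double x, double L) { return x - L * std::floor(x / L); }
inline double mini(double d, double L) { return d - L * std::round(d / L); }

void cells_to_faces(const Model& m, const std::vector<double>& f,
                    std::vector<double>& fx, std::vector<double>& fy) {
  for (int j = 0; j < m.ny; ++j) {
    int jp = (j + 1) % m.ny;
    for (int i = 0; i < m.nx; ++i) {
      int ip = (i + 1) % m.nx;
      fx[m.id(i, j)] = 0.5 * (f[m.id(i, j)] + f[m.id(ip, j)]);
      fy[m.id(i, j)] = 0.5 * (f[m.id(i, j)] + f[m.id(i, jp)]);
    }
  }
}

void gradient(const Model& m, const std::vector<double>& f,
              std::vector<double>& gx, std::vector<double>& gy) {
  for (int j = 0; j < m.ny; ++j) {
    int jp = (j + 1) % m.ny;
    for (int i = 0; i < m.nx; ++i) {
      int ip = (i + 1) % m.nx;
      gx[m.id(i, j)] = (f[m.id(ip, j)] - f[m.id(i, j)]) / m.dx;
      gy[m.id(i, j)] = (f[m.id(i, jp)] - f[m.id(i, j)]) / m.dx;
    }
  }
}

void divergence(const Model& m, const std::vector<double>& jx,
                const std::vector<double>& jy, std::vector<double>& out,
                bool add) {
  for (int j = 0; j < m.ny; ++j) {
    int jm = (j + m.ny - 1) % m.ny;
    for (int i = 0; i < m.nx; ++i) {
      int im = (i + m.nx - 1) % m.nx;
      double v = (jx[m.id(i, j)] - jx[m.id(im, j)] +
                  jy[m.id(i, j)] - jy[m.id(i, jm)]) / m.dx;
      if (add) out[m.id(i, j)] += v; else out[m.id(i, j)] = v;
    }
  }
}

void faces_to_cells(const Model& m, const std::vector<double>& jx,
                    const std::vector<double>& jy, std::vector<double>& out) {
  for (int j = 0; j < m.ny; ++j) {
    int jm = (j + m.ny - 1) % m.ny;
    for (int i = 0; i < m.nx; ++i) {
      int im = (i + m.nx - 1) % m.nx;
      out[m.id(i, j)] = 0.5 * (jx[m.id(i, j)] + jx[m.id(im, j)] +
                               jy[m.id(i, j)] + jy[m.id(i, jm)]);
    }
  }
}

inline double cc(int i, double dx) { return (i + 0.5) * dx; }

// interaction kernel eta(x_m - X) over the grid (amplitude amp, width s0)
void kernel_field(const Model& m, double Xa, double Xb, double amp,
                  double s0, double rcut, std::vector<double>& out) {
  double Z = 2.0 * M_PI * s0 * s0, r2c = rcut * rcut;
  for (int j = 0; j < m.ny; ++j) {
    double sy = mini(cc(j, m.dx) - Xb, m.Ly);
    for (int i = 0; i < m.nx; ++i) {
      double sx = mini(cc(i, m.dx) - Xa, m.Lx);
      double r2 = sx * sx + sy * sy;
      out[m.id(i, j)] = (r2 <= r2c) ? amp / Z * std::exp(-r2 / (2 * s0 * s0))
                                    : 0.0;
    }
  }
}

// protein force -dPsi/dX - c0 dV sum_m (dPhi/dX) q_m
void force(const Model& m, const State& s, double& Fx, double& Fy) {
  Fx = 0.0; Fy = 0.0;
  if (!s.hasX) return;
  if (m.pot_type == 1) {
    Fx = -m.pk * mini(s.X0 - m.pcx, m.Lx);
    Fy = -m.pk * mini(s.X1 - m.pcy, m.Ly);
  } else if (m.pot_type == 3) {
    for (size_t w = 0; w < m.wx.size(); ++w) {
      double dx = mini(s.X0 - m.wx[w], m.Lx), dy = mini(s.X1 - m.wy[w], m.Ly);
      double e = std::exp(-(dx * dx + dy * dy) / (2 * m.sigma0w * m.sigma0w));
      Fx += -m.c2 * dx / (m.sigma0w * m.sigma0w) * e;
      Fy += -m.c2 * dy / (m.sigma0w * m.sigma0w) * e;
    }
  }
  if (m.pot_type == 2 && s.hasQ) {
    // dPhi/dX = psign * (s/sigma0^2) * eta(s),  F -= c0 dV dPhi/dX q
    double Z = 2.0 * M_PI * m.sigma0 * m.sigma0, r2c = m.rcut * m.rcut;
    double ax = 0.0, ay = 0.0;
    for (int j = 0; j < m.ny; ++j) {
      double sy = mini(cc(j, m.dx) - s.X1, m.Ly);
      for (int i = 0; i < m.nx; ++i) {
        double sx = mini(cc(i, m.dx) - s.X0, m.Lx);
        double r2 = sx * sx + sy * sy;
        if (r2 > r2c) continue;
        double eta = m.k1 / Z * std::exp(-r2 / (2 * m.sigma0 * m.sigma0));
        double w = m.psign / (m.sigma0 * m.sigma0) * eta * s.q[m.id(i, j)];
        ax += sx * w; ay += sy * w;
      }
    }
    Fx -= m.c0 * m.dV * ax;
    Fy -= m.c0 * m.dV * ay;
  }
}

struct Drift {
  double X0 = 0, X1 = 0, thP = 0, thI = 0;
  std::vector<double> q, thC;
};

void drift(const Model& m, const State& s, Drift& a, Fields& w,
           std::vector<double>& kci, std::vector<double>& phi) {
  int N = m.nx * m.ny;
  double Fx = 0, Fy = 0;
  force(m, s, Fx, Fy);
  bool havePhi = (m.pot_type == 2) && s.hasX && s.hasQ;
  if (havePhi)
    kernel_field(m, s.X0, s.X1, m.psign * m.k1, m.sigma0, m.rcut, phi);

  // face diffusivity thetaC_f / gamma (theta0 when thetaC absent)
  std::vector<double>& kfx = w.fx; std::vector<double>& kfy = w.fy;
  if (s.hasC) {
    cells_to_faces(m, s.thC, kfx, kfy);
    for (int k = 0; k < N; ++k) { kfx[k] /= m.gamma; kfy[k] /= m.gamma; }
  } else {
    std::fill(kfx.begin(), kfx.end(), m.theta0 / m.gamma);
    std::fill(kfy.begin(), kfy.end(), m.theta0 / m.gamma);
  }

  if (m.evX && s.hasX) { a.X0 = Fx / m.gamma_p; a.X1 = Fy / m.gamma_p; }

  std::vector<double> gpx, gpy, qfx, qfy;
  if (havePhi) {
    gpx.resize(N); gpy.resize(N); qfx.resize(N); qfy.resize(N);
    gradient(m, phi, gpx, gpy);
    cells_to_faces(m, s.q, qfx, qfy);
  }

  if (m.evQ && s.hasQ) {
    gradient(m, s.q, w.gx, w.gy);
    std::vector<double>& jx = w.c1; std::vector<double>& jy = w.c2;
    jx.assign(N, 0.0); jy.assign(N, 0.0);
    for (int k = 0; k < N; ++k) {
      jx[k] = kfx[k] * w.gx[k];
      jy[k] = kfy[k] * w.gy[k];
      if (havePhi) {
        jx[k] += qfx[k] / m.gamma * gpx[k];
        jy[k] += qfy[k] / m.gamma * gpy[k];
      }
    }
    divergence(m, jx, jy, a.q, false);
  }

  bool haveKci = m.kCI > 0 && m.has_ifk && s.hasX;
  if (haveKci) kernel_field(m, s.X0, s.X1, m.kCI, m.ifk_s0, m.ifk_rcut, kci);

  if (m.evC && s.hasC) {
    gradient(m, s.thC, w.gx, w.gy);
    std::vector<double>& jx = w.c1; std::vector<double>& jy = w.c2;
    for (int k = 0; k < N; ++k) { jx[k] = m.kCC * w.gx[k]; jy[k] = m.kCC * w.gy[k]; }
    divergence(m, jx, jy, a.thC, false);
    for (int k = 0; k < N; ++k) a.thC[k] /= m.CC;
    if (haveKci && s.hasT)
      for (int k = 0; k < N; ++k)
        a.thC[k] -= kci[k] / m.CC * (s.thC[k] - s.thI);
    if (m.k0 > 0)
      for (int k = 0; k < N; ++k)
        a.thC[k] -= m.k0 / m.CC * (s.thC[k] - m.bath[k]);
    if (havePhi) {
      // face-centered heating reclaiming the species-flux losses
      gradient(m, s.q, w.gx, w.gy);
      std::vector<double> hx(N), hy(N), hc(N);
      for (int k = 0; k < N; ++k) {
        hx[k] = m.c0 * kfx[k] * gpx[k] * w.gx[k] +
                m.c0 * qfx[k] / m.gamma * gpx[k] * gpx[k];
        hy[k] = m.c0 * kfy[k] * gpy[k] * w.gy[k] +
                m.c0 * qfy[k] / m.gamma * gpy[k] * gpy[k];
      }
      faces_to_cells(m, hx, hy, hc);
      for (int k = 0; k < N; ++k) a.thC[k] += hc[k] / m.CC;
    }
  }

  if (m.evT && s.hasT) {
    a.thP = -m.kPI / m.CP * (s.thP - s.thI);
    if (m.evX && s.hasX)
      a.thP += (Fx * Fx + Fy * Fy) / (m.gamma_p * m.CP);
    a.thI = m.kPI / m.CI * (s.thP - s.thI);
    if (haveKci && s.hasC) {
      double acc = 0.0;
      for (int k = 0; k < N; ++k) acc += kci[k] * (s.thC[k] - s.thI);
      a.thI += acc * m.dV / m.CI;
    }
  }
}

struct Xi {
  bool protein = false, qb = false, cond = false, PI = false, IC = false,
       amb = false;
  std::vector<double> xp, qx, qy, cx, cy, ic, am;
  double pi = 0;
};

void draw_xi(const Model& m, const State& s, Xi& xi) {
  int N = m.nx * m.ny;
  xi.protein = xi.qb = xi.cond = xi.PI = xi.IC = xi.amb = false;
  if (!m.noise || m.kB <= 0) return;
  // canonical block order; matches the R draw order exactly
  if (m.evX && s.hasX) {
    xi.protein = true; xi.xp = as<std::vector<double>>(rnorm(2));
  }
  if (m.evQ && s.hasQ) {
    xi.qb = true;
    xi.qx = as<std::vector<double>>(rnorm(N));
    xi.qy = as<std::vector<double>>(rnorm(N));
  }
  if (m.evC && s.hasC && m.kCC > 0) {
    xi.cond = true;
    xi.cx = as<std::vector<double>>(rnorm(N));
    xi.cy = as<std::vector<double>>(rnorm(N));
  }
  if (m.evT && s.hasT && m.kPI > 0) {
    xi.PI = true; xi.pi = R::norm_rand();
  }
  if (m.evT && m.evC && s.hasC && m.kCI > 0 && s.hasX && m.has_ifk) {
    xi.IC = true; xi.ic = as<std::vector<double>>(rnorm(N));
  }
  if (m.evC && s.hasC && m.k0 > 0) {
    xi.amb = true; xi.am = as<std::vector<double>>(rnorm(N));
  }
}

struct Noise {
  double X0 = 0, X1 = 0, thP = 0, thI = 0;
  std::vector<double> q, thC;
};

void apply_noise(const Model& m, const State& s, const Xi& xi, double dt,
                 Noise& h, Fields& w, std::vector<double>& kci) {
  int N = m.nx * m.ny;
  double amp = std::sqrt(2.0 * m.kB * dt);
  h.X0 = h.X1 = h.thP = h.thI = 0.0;
  std::fill(h.q.begin(), h.q.end(), 0.0);
  std::fill(h.thC.begin(), h.thC.end(), 0.0);
  if (!m.noise || m.kB <= 0) return;

  std::vector<double>& tfx = w.fx; std::vector<double>& tfy = w.fy;
  if (s.hasC) cells_to_faces(m, s.thC, tfx, tfy);
  else {
    std::fill(tfx.begin(), tfx.end(), m.theta0);
    std::fill(tfy.begin(), tfy.end(), m.theta0);
  }

  if (xi.protein) {
    double thP = s.hasT ? s.thP : m.theta0;
    double a = amp * std::sqrt(thP / m.gamma_p);
    h.X0 = a * xi.xp[0]; h.X1 = a * xi.xp[1];
  }
  if (xi.qb) {
    std::vector<double>& cfx = w.c1; std::vector<double>& cfy = w.c2;
    cfx.resize(N); cfy.resize(N);
    std::vector<double> qfx(N), qfy(N), qp(N);
    for (int k = 0; k < N; ++k) qp[k] = std::max(s.q[k], 0.0);
    cells_to_faces(m, qp, qfx, qfy);
    for (int k = 0; k < N; ++k) {
      cfx[k] = std::sqrt(tfx[k] * qfx[k] / (m.gamma * m.c0 * m.dV)) * xi.qx[k];
      cfy[k] = std::sqrt(tfy[k] * qfy[k] / (m.gamma * m.c0 * m.dV)) * xi.qy[k];
    }
    divergence(m, cfx, cfy, h.q, false);
    for (int k = 0; k < N; ++k) h.q[k] *= amp;
  }
  if (xi.cond) {
    std::vector<double>& cfx = w.c1; std::vector<double>& cfy = w.c2;
    cfx.resize(N); cfy.resize(N);
    double sc = std::sqrt(m.kCC / m.dV);
    for (int k = 0; k < N; ++k) {
      cfx[k] = sc * tfx[k] * xi.cx[k];
      cfy[k] = sc * tfy[k] * xi.cy[k];
    }
    divergence(m, cfx, cfy, h.thC, false);
    for (int k = 0; k < N; ++k) h.thC[k] *= amp / m.CC;
  }
  if (xi.PI) {
    double a = amp * std::sqrt(m.kPI * s.thP * s.thI) * xi.pi;
    h.thP += a / m.CP;
    h.thI -= a / m.CI;
  }
  if (xi.IC) {
    kernel_field(m, s.X0, s.X1, m.kCI, m.ifk_s0, m.ifk_rcut, kci);
    double acc = 0.0;
    for (int k = 0; k < N; ++k) {
      double a = amp * std::sqrt(kci[k] * m.dV * s.thI * s.thC[k]) * xi.ic[k];
      h.thC[k] += a / (m.CC * m.dV);
      acc += a;
    }
    h.thI -= acc / m.CI;
  }
  if (xi.amb) {
    for (int k = 0; k < N; ++k)
      h.thC[k] += amp *
        std::sqrt(m.k0 * s.thC[k] * m.bath[k] / m.dV) / m.CC * xi.am[k];
  }
}

bool state_valid(const State& s) {
  if (s.hasT && (!std::isfinite(s.thP) || s.thP <= 0 ||
                 !std::isfinite(s.thI) || s.thI <= 0)) return false;
  if (s.hasC)
    for (double v : s.thC)
      if (!std::isfinite(v) || v <= 0) return false;
  if (s.hasQ) {
    double qmin = R_PosInf, qmax = 1e-12;
    for (double v : s.q) {
      if (!std::isfinite(v)) return false;
      if (v < qmin) qmin = v;
      if (v > qmax) qmax = v;
    }
    if (!(qmin > -1e-3 * qmax)) return false;
  }
  if (s.hasX && (!std::isfinite(s.X0) || !std::isfinite(s.X1))) return false;
  return true;
}

void axpy(const Model& m, const State& s, const Drift& a1, const Drift& a2,
          double wdrift, const Noise* h1, const Noise* h2, double dt,
          State& out) {
  // out = s + wdrift*(a1 [+ a2]) * dt + (h1 [+ h2]) * 0.5-style weights
  int N = m.nx * m.ny;
  out = s;
  double hx = 0, hy = 0, hp = 0, hi = 0;
  if (h1) { hx += h1->X0; hy += h1->X1; hp += h1->thP; hi += h1->thI; }
  if (h2) { hx = 0.5 * (h1->X0 + h2->X0); hy = 0.5 * (h1->X1 + h2->X1);
            hp = 0.5 * (h1->thP + h2->thP); hi = 0.5 * (h1->thI + h2->thI); }
  if (s.hasX) {
    double aX0 = h2 ? 0.5 * (a1.X0 + a2.X0) : a1.X0;
    double aX1 = h2 ? 0.5 * (a1.X1 + a2.X1) : a1.X1;
    out.X0 = wrapc(s.X0 + m.evX * (aX0 * dt) + hx, m.Lx);
    out.X1 = wrapc(s.X1 + m.evX * (aX1 * dt) + hy, m.Ly);
  }
  if (s.hasT && m.evT) {
    out.thP = s.thP + (h2 ? 0.5 * (a1.thP + a2.thP) : a1.thP) * dt + hp;
    out.thI = s.thI + (h2 ? 0.5 * (a1.thI + a2.thI) : a1.thI) * dt + hi;
  }
  if (s.hasQ && m.evQ)
    for (int k = 0; k < N; ++k)
      out.q[k] = s.q[k] + (h2 ? 0.5 * (a1.q[k] + a2.q[k]) : a1.q[k]) * dt +
        (h2 ? 0.5 * (h1->q[k] + h2->q[k]) : (h1 ? h1->q[k] : 0.0));
  if (s.hasC && m.evC)
    for (int k = 0; k < N; ++k)
      out.thC[k] = s.thC[k] +
        (h2 ? 0.5 * (a1.thC[k] + a2.thC[k]) : a1.thC[k]) * dt +
        (h2 ? 0.5 * (h1->thC[k] + h2->thC[k]) : (h1 ? h1->thC[k] : 0.0));
}

struct Work {
  Drift a1, a2;
  Noise h1, h2;
  Xi xi;
  Fields w;
  std::vector<double> kci, phi;
  State pred, cand, half;
  long rejections = 0;
};

bool step(const Model& m, const State& s, double dt, int depth, Work& wk,
          State& out);

bool step_once(const Model& m, const State& s, double dt, Work& wk,
               State& out) {
  drift(m, s, wk.a1, wk.w, wk.kci, wk.phi);
  draw_xi(m, s, wk.xi);
  apply_noise(m, s, wk.xi, dt, wk.h1, wk.w, wk.kci);
  axpy(m, s, wk.a1, wk.a1, 1.0, &wk.h1, nullptr, dt, wk.pred);
  if (!state_valid(wk.pred)) return false;
  drift(m, wk.pred, wk.a2, wk.w, wk.kci, wk.phi);
  apply_noise(m, wk.pred, wk.xi, dt, wk.h2, wk.w, wk.kci);
  axpy(m, s, wk.a1, wk.a2, 0.5, &wk.h1, &wk.h2, dt, out);
  return state_valid(out);
}

bool step(const Model& m, const State& s, double dt, int depth, Work& wk,
          State& out) {
  if (step_once(m, s, dt, wk, out)) return true;
  wk.rejections++;
  if (depth <= 0) return false;
  State half = s;
  if (!step(m, s, dt / 2, depth - 1, wk, half)) return false;
  return step(m, half, dt / 2, depth - 1, wk, out);
}

Model build_model(const List& spec) {
  Model m;
  m.nx = spec["nx"]; m.ny = spec["ny"]; m.dx = spec["dx"];
  m.dV = m.dx * m.dx; m.Lx = m.nx * m.dx; m.Ly = m.ny * m.dx;
  m.kB = spec["kB"]; m.c0 = spec["c0"]; m.gamma = spec["gamma"];
  m.gamma_p = spec["gamma_p"]; m.kPI = spec["kappaPI"];
  m.kCI = spec["kappaCI"]; m.kCC = spec["kappaCC"]; m.k0 = spec["kappa0"];
  m.CP = spec["C_P"]; m.CC = spec["C_C"]; m.CI = spec["C_I"];
  m.theta0 = spec["theta0"];
  m.evX = spec["evX"]; m.evQ = spec["evQ"]; m.evT = spec["evT"];
  m.evC = spec["evC"];
  m.pot_type = spec["pot_type"];
  m.pk = spec["pot_k"]; m.pcx = spec["pot_cx"]; m.pcy = spec["pot_cy"];
  m.k1 = spec["pot_k1"]; m.sigma0 = spec["pot_sigma0"];
  m.rcut = spec["pot_rcut"]; m.psign = spec["pot_sign"];
  m.c2 = spec["pot_c2"]; m.sigma0w = spec["pot_sigma0w"];
  m.wx = as<std::vector<double>>(spec["well_x"]);
  m.wy = as<std::vector<double>>(spec["well_y"]);
  m.has_ifk = spec["has_ifk"];
  m.ifk_s0 = spec["ifk_sigma0"]; m.ifk_rcut = spec["ifk_rcut"];
  m.bath = as<std::vector<double>>(spec["bath"]);
  m.noise = spec["noise"];
  return m;
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_selm(List spec, List state0, double dt, int n_steps,
                  int record_stride, int field_stride, double escape_r0,
                  NumericVector escape_center) {
  Model m = build_model(spec);
  int N = m.nx * m.ny;

  State s;
  s.hasX = state0.containsElementNamed("X") &&
           !Rf_isNull(state0["X"]);
  s.hasQ = state0.containsElementNamed("q") && !Rf_isNull(state0["q"]);
  s.hasT = state0.containsElementNamed("thetaP") &&
           !Rf_isNull(state0["thetaP"]);
  s.hasC = state0.containsElementNamed("thetaC") &&
           !Rf_isNull(state0["thetaC"]);
  if (s.hasX) {
    NumericVector X = state0["X"];
    s.X0 = X[0]; s.X1 = X[1];
  }
  if (s.hasQ) s.q = as<std::vector<double>>(state0["q"]);
  if (s.hasT) { s.thP = state0["thetaP"]; s.thI = state0["thetaI"]; }
  if (s.hasC) s.thC = as<std::vector<double>>(state0["thetaC"]);

  Work wk;
  wk.w.fx.resize(N); wk.w.fy.resize(N); wk.w.gx.resize(N); wk.w.gy.resize(N);
  wk.w.c1.resize(N); wk.w.c2.resize(N);
  wk.kci.resize(N); wk.phi.resize(N);
  wk.a1.q.resize(N); wk.a1.thC.resize(N);
  wk.a2.q.resize(N); wk.a2.thC.resize(N);
  wk.h1.q.resize(N); wk.h1.thC.resize(N);
  wk.h2.q.resize(N); wk.h2.thC.resize(N);

  int n_rec = (record_stride > 0) ? n_steps / record_stride : 0;
  NumericMatrix Xrec(std::max(n_rec, 0), 2);
  NumericVector trec(std::max(n_rec, 0)), thPrec(std::max(n_rec, 0)),
      thIrec(std::max(n_rec, 0));
  int n_frec = (field_stride > 0) ? n_steps / field_stride : 0;
  NumericMatrix qrec(s.hasQ ? N : 0, s.hasQ ? n_frec : 0);
  NumericMatrix crec(s.hasC ? N : 0, s.hasC ? n_frec : 0);
  NumericVector tfrec(std::max(n_frec, 0));

  RNGScope rng;
  double t = 0.0, escape_time = NA_REAL;
  int irec = 0, ifrec = 0;
  State next = s;
  for (int n = 1; n <= n_steps; ++n) {
    if (!step(m, s, dt, 5, wk, next))
      stop("integrator: positivity violation persists after 5 halvings");
    s = next;
    t = n * dt;
    if (record_stride > 0 && n % record_stride == 0 && irec < n_rec) {
      trec[irec] = t;
      if (s.hasX) { Xrec(irec, 0) = s.X0; Xrec(irec, 1) = s.X1; }
      if (s.hasT) { thPrec[irec] = s.thP; thIrec[irec] = s.thI; }
      ++irec;
    }
    if (field_stride > 0 && n % field_stride == 0 && ifrec < n_frec) {
      tfrec[ifrec] = t;
      if (s.hasQ) for (int k = 0; k < N; ++k) qrec(k, ifrec) = s.q[k];
      if (s.hasC) for (int k = 0; k < N; ++k) crec(k, ifrec) = s.thC[k];
      ++ifrec;
    }
    if (escape_r0 > 0 && s.hasX) {
      double dx = mini(s.X0 - escape_center[0], m.Lx);
      double dy = mini(s.X1 - escape_center[1], m.Ly);
      if (std::sqrt(dx * dx + dy * dy) >= escape_r0) {
        escape_time = t;
        break;
      }
    }
  }

  List fin = List::create(
      _["X"] = s.hasX ? (SEXP)NumericVector::create(s.X0, s.X1) : R_NilValue,
      _["q"] = s.hasQ ? (SEXP)wrap(s.q) : R_NilValue,
      _["thetaP"] = s.hasT ? (SEXP)wrap(s.thP) : R_NilValue,
      _["thetaI"] = s.hasT ? (SEXP)wrap(s.thI) : R_NilValue,
      _["thetaC"] = s.hasC ? (SEXP)wrap(s.thC) : R_NilValue);

  return List::create(
      _["final"] = fin, _["t"] = trec, _["X"] = Xrec,
      _["thetaP"] = thPrec, _["thetaI"] = thIrec,
      _["t_fields"] = tfrec, _["q_fields"] = qrec, _["thetaC_fields"] = crec,
      _["escape_time"] = escape_time, _["time"] = t,
      _["n_rejections"] = (double)wk.rejections,
      _["n_recorded"] = irec, _["n_field_recorded"] = ifrec);
}
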