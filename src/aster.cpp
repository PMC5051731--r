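#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Simplified 2D overdamped engine for MTOC asters: dynamic-instability
// filaments anchored on rigid MTOC bodies, surface-immobilized minus-end
// directed motors with Kramers force-dependent detachment, and diffusible
// two-headed cross-linking motor complexes.
//
// Mechanics (documented in the methods vignette): filament contour length is
// controlled solely by dynamic instability; within a step vertices move under
// explicit local forces, the contour is then re-projected to exact segment
// rest lengths from the anchored minus end outward (follow-the-leader), and
// consecutive segments relax toward alignment at the overdamped bending rate
// kappa/(L_seg^3 * gamma_v). Aster translation is rigid: the summed force on
// all vertices plus the body, over the summed drag. Per-filament cortical
// confinement force is capped at the Euler buckling load pi^2*kappa/(4 L^2).
//
// Units: um, s, pN (eta in pN s/um^2, kappa in pN um^2, kBT in pN um).
// ---------------------------------------------------------------------------

namespace {

struct Filament {
  int mtoc;
  double ax, ay;          // unit anchor direction in the (non-rotating) body frame
  double len;             // contour length
  bool growing;
  std::vector<double> vx, vy;   // vertices, [0] = minus-end anchor
  std::vector<double> fx, fy;   // per-step force accumulator (shape update)
  double conf_fx, conf_fy;      // confinement part (for the Euler cap)
  double rig_fx, rig_fy;        // motor/complex forces: rigid translation only
                                // (the stiff spring term is unstable in the
                                // per-vertex overdamped update at dt = 0.01)
};

struct Motor {            // surface-immobilized, one head
  double x, y;
  int fil;                // -1 = unbound
  double a;               // abscissa from the minus end
};

struct Complex {          // diffusible two-headed cross-linker
  double x, y;
  int fil1, fil2;
  double a1, a2;
};

struct Engine {
  double r_cell, r_chr, eta, kappa, kBT;
  double seg, dt;
  double vg_c, vs_c, fcat_c, fres_c;      // cytoplasmic DI
  double vg_s, vs_s, fcat_s, fres_s;      // stabilized DI
  bool di_gradient;
  bool a_on; double a_rhalf, a_s;         // attractive field (gradient mapping)
  double k_mot, v_m, f0, r_attach, r_detach0, r_detach_end, d_attach, D_c;
  double k_conf;
  double mtoc_radius;
  double gamma_v, gamma_body;

  std::vector<double> mx, my;             // MTOC centres
  std::vector<Filament> fils;
  std::vector<Motor> motors;
  std::vector<Complex> cplx;

  // spatial hash over filament segments
  double cell_sz; int ncell;
  std::vector<std::vector<int>> grid;     // segment ids: fil*4096 unusable; use pairs
  std::vector<int> seg_fil, seg_idx;      // flattened segment registry
  std::vector<int> touched;

  double max_pair_imbalance;              // momentum bookkeeping diagnostic
  long bind_events;
  double cum_motor_fr, cum_conf_fr;       // cumulative radial force on MTOC 0
};

inline double phi_a_at(const Engine &E, double x, double y) {
  double r = std::max(0.0, std::hypot(x, y) - E.r_chr);
  return 1.0 / (1.0 + std::exp((r - E.a_rhalf) / E.a_s));
}

inline int n_seg_of(const Engine &E, const Filament &f) {
  return std::max(1, (int)std::ceil(f.len / E.seg - 1e-12));
}

inline double rest_len(const Engine &E, const Filament &f, int i) {
  int ns = n_seg_of(E, f);
  if (i < ns - 1) return E.seg;
  return f.len - E.seg * (ns - 1);
}

// piecewise linear force-velocity: full speed for assisting/zero load,
// linear ramp to stall for opposing load
inline double load_velocity(double f_op, double f0, double v_m) {
  if (f_op <= 0.0) return v_m;
  if (f_op >= f0) return 0.0;
  return v_m * (1.0 - f_op / f0);
}

// point on the filament contour at abscissa a, plus local tangent
inline void point_at(const Engine &E, const Filament &f, double a,
                     double &px, double &py, double &tx, double &ty,
                     int &iseg, double &w) {
  int ns = n_seg_of(E, f);
  double acc = 0.0;
  iseg = ns - 1; w = 1.0;
  for (int i = 0; i < ns; ++i) {
    double L = rest_len(E, f, i);
    if (a <= acc + L || i == ns - 1) {
      iseg = i;
      w = (L > 0.0) ? std::min(1.0, std::max(0.0, (a - acc) / L)) : 0.0;
      break;
    }
    acc += L;
  }
  double x0 = f.vx[iseg], y0 = f.vy[iseg];
  double x1 = f.vx[iseg + 1], y1 = f.vy[iseg + 1];
  px = x0 + w * (x1 - x0); py = y0 + w * (y1 - y0);
  double dx = x1 - x0, dy = y1 - y0, n = std::hypot(dx, dy);
  if (n > 0) { tx = dx / n; ty = dy / n; } else { tx = 1.0; ty = 0.0; }
}

// motor and cross-linker spring forces act on the aster as a rigid body
inline void apply_at(Filament &f, int iseg, double w, double Fx, double Fy) {
  (void)iseg; (void)w;
  f.rig_fx += Fx; f.rig_fy += Fy;
}

inline int grid_cell(const Engine &E, double x, double y) {
  int ix = (int)std::floor((x + E.r_cell) / E.cell_sz);
  int iy = (int)std::floor((y + E.r_cell) / E.cell_sz);
  ix = std::min(std::max(ix, 0), E.ncell - 1);
  iy = std::min(std::max(iy, 0), E.ncell - 1);
  return iy * E.ncell + ix;
}

void rebuild_grid(Engine &E) {
  for (int c : E.touched) E.grid[c].clear();
  E.touched.clear();
  E.seg_fil.clear(); E.seg_idx.clear();
  for (size_t k = 0; k < E.fils.size(); ++k) {
    Filament &f = E.fils[k];
    int ns = n_seg_of(E, f);
    for (int i = 0; i < ns; ++i) {
      double mxx = 0.5 * (f.vx[i] + f.vx[i + 1]);
      double myy = 0.5 * (f.vy[i] + f.vy[i + 1]);
      int c = grid_cell(E, mxx, myy);
      if (E.grid[c].empty()) E.touched.push_back(c);
      E.grid[c].push_back((int)E.seg_fil.size());
      E.seg_fil.push_back((int)k); E.seg_idx.push_back(i);
    }
  }
}

// nearest contour point within d_attach of (x, y); returns filament id or -1
int find_attach(const Engine &E, double x, double y, int exclude1, int exclude2,
                double &a_out) {
  int best = -1; double best_d2 = E.d_attach * E.d_attach; double best_a = 0.0;
  int ix = (int)std::floor((x + E.r_cell) / E.cell_sz);
  int iy = (int)std::floor((y + E.r_cell) / E.cell_sz);
  for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
    int jx = ix + dx, jy = iy + dy;
    if (jx < 0 || jy < 0 || jx >= E.ncell || jy >= E.ncell) continue;
    for (int sid : E.grid[jy * E.ncell + jx]) {
      int fi = E.seg_fil[sid], si = E.seg_idx[sid];
      if (fi == exclude1 || fi == exclude2) continue;
      const Filament &f = E.fils[fi];
      double x0 = f.vx[si], y0 = f.vy[si], x1 = f.vx[si + 1], y1 = f.vy[si + 1];
      double dxs = x1 - x0, dys = y1 - y0;
      double L2 = dxs * dxs + dys * dys;
      double w = (L2 > 0.0) ? ((x - x0) * dxs + (y - y0) * dys) / L2 : 0.0;
      w = std::min(1.0, std::max(0.0, w));
      double px = x0 + w * dxs, py = y0 + w * dys;
      double d2 = (x - px) * (x - px) + (y - py) * (y - py);
      if (d2 < best_d2) {
        best_d2 = d2; best = fi;
        double acc = 0.0;
        for (int q = 0; q < si; ++q) acc += rest_len(E, f, q);
        best_a = acc + w * rest_len(E, f, si);
      }
    }
  }
  a_out = best_a;
  return best;
}

void di_step_engine(Engine &E) {
  for (Filament &f : E.fils) {
    double fcat = E.fcat_c, fres = E.fres_c, vg = E.vg_c, vs = E.vs_c;
    if (E.di_gradient) {
      int nv = (int)f.vx.size();
      double phi = phi_a_at(E, f.vx[nv - 1], f.vy[nv - 1]);  // plus-end tip
      fcat = phi * E.fcat_s + (1.0 - phi) * E.fcat_c;
      fres = phi * E.fres_s + (1.0 - phi) * E.fres_c;
      vg = phi * E.vg_s + (1.0 - phi) * E.vg_c;
      vs = phi * E.vs_s + (1.0 - phi) * E.vs_c;
    }
    if (f.growing) {
      f.len += vg * E.dt;
      if (R::unif_rand() < 1.0 - std::exp(-fcat * E.dt)) f.growing = false;
    } else {
      f.len -= vs * E.dt;
      if (f.len <= 1e-3) { f.len = 1e-3; f.growing = true; }  // persistent nucleation
      else if (R::unif_rand() < 1.0 - std::exp(-fres * E.dt)) f.growing = true;
    }
    // re-discretize: add/remove tip vertices to match ceil(len/seg)+1
    int ns = n_seg_of(E, f);
    int nv_target = ns + 1;
    while ((int)f.vx.size() < nv_target) {
      size_t n = f.vx.size();
      double dx, dy;
      if (n >= 2) { dx = f.vx[n - 1] - f.vx[n - 2]; dy = f.vy[n - 1] - f.vy[n - 2]; }
      else { dx = f.ax; dy = f.ay; }
      double nn = std::hypot(dx, dy);
      if (nn < 1e-12) { dx = f.ax; dy = f.ay; nn = 1.0; }
      f.vx.push_back(f.vx[n - 1] + dx / nn * E.seg);
      f.vy.push_back(f.vy[n - 1] + dy / nn * E.seg);
    }
    while ((int)f.vx.size() > nv_target) { f.vx.pop_back(); f.vy.pop_back(); }
    f.fx.assign(f.vx.size(), 0.0); f.fy.assign(f.vy.size(), 0.0);
    f.conf_fx = 0.0; f.conf_fy = 0.0; f.rig_fx = 0.0; f.rig_fy = 0.0;
  }
}

void confinement_forces(Engine &E) {
  for (Filament &f : E.fils) {
    double sfx = 0.0, sfy = 0.0;
    std::vector<double> cfx(f.vx.size(), 0.0), cfy(f.vy.size(), 0.0);
    for (size_t i = 0; i < f.vx.size(); ++i) {
      double r = std::hypot(f.vx[i], f.vy[i]);
      if (r > E.r_cell && r > 0.0) {
        double pen = r - E.r_cell;
        double Fm = E.k_conf * pen;
        cfx[i] = -Fm * f.vx[i] / r; cfy[i] = -Fm * f.vy[i] / r;
        sfx += cfx[i]; sfy += cfy[i];
      }
    }
    double Fs = std::hypot(sfx, sfy);
    if (Fs > 0.0) {
      // growing MTs push by buckling-limited polymerization force
      double L = std::max(f.len, E.seg);
      double f_euler = M_PI * M_PI * E.kappa / (4.0 * L * L);
      double scale = (Fs > f_euler) ? f_euler / Fs : 1.0;
      for (size_t i = 0; i < f.vx.size(); ++i) {
        f.fx[i] += scale * cfx[i]; f.fy[i] += scale * cfy[i];
      }
      f.conf_fx = scale * sfx; f.conf_fy = scale * sfy;
    }
  }
}

void motor_step(Engine &E) {
  const double p_att = 1.0 - std::exp(-E.r_attach * E.dt);
  for (Motor &m : E.motors) {
    if (m.fil < 0) {
      if (R::unif_rand() < p_att) {
        double a;
        int fi = find_attach(E, m.x, m.y, -1, -1, a);
        if (fi >= 0) { m.fil = fi; m.a = a; ++E.bind_events; }
      }
      continue;
    }
    Filament &f = E.fils[m.fil];
    if (m.a > f.len) m.a = f.len;           // filament shrank past the head
    double px, py, tx, ty; int iseg; double w;
    point_at(E, f, m.a, px, py, tx, ty, iseg, w);
    double ex = px - m.x, ey = py - m.y;    // spring extension
    double Fx = -E.k_mot * 1e3 * ex, Fy = -E.k_mot * 1e3 * ey;  // k in pN/nm -> pN/um
    double fmag = std::hypot(Fx, Fy);
    apply_at(f, iseg, w, Fx, Fy);
    // reaction on the rigid anchor; bookkeeping check only
    E.max_pair_imbalance = std::max(E.max_pair_imbalance,
                                    std::hypot(Fx + (-Fx), Fy + (-Fy)));
    bool at_end = (m.a <= 1e-9) || (m.a >= f.len - 1e-9);
    double rate = (at_end ? E.r_detach_end : E.r_detach0) * std::exp(fmag / E.f0);
    if (R::unif_rand() < 1.0 - std::exp(-rate * E.dt)) { m.fil = -1; continue; }
    // walk toward the minus end; opposing load = spring force component
    // along +tangent (resisting minus-ward motion)
    double f_op = Fx * tx + Fy * ty;
    double v = load_velocity(f_op, E.f0, E.v_m);
    m.a = std::max(0.0, m.a - v * E.dt);
  }
}

void complex_step(Engine &E, bool &any) {
  const double p_att = 1.0 - std::exp(-E.r_attach * E.dt);
  const double sd = std::sqrt(2.0 * E.D_c * E.dt);
  any = false;
  for (Complex &c : E.cplx) {
    // resolve heads invalidated by shrinkage
    if (c.fil1 >= 0 && c.a1 > E.fils[c.fil1].len) c.a1 = E.fils[c.fil1].len;
    if (c.fil2 >= 0 && c.a2 > E.fils[c.fil2].len) c.a2 = E.fils[c.fil2].len;

    if (c.fil1 < 0 && c.fil2 < 0) {
      c.x += R::norm_rand() * sd; c.y += R::norm_rand() * sd;
      double r = std::hypot(c.x, c.y);
      if (r > E.r_cell && r > 0.0) {  // reflect at the cortex
        double rr = std::max(0.0, 2.0 * E.r_cell - r);
        c.x *= rr / r; c.y *= rr / r;
      }
      if (R::unif_rand() < p_att) {
        double a; int fi = find_attach(E, c.x, c.y, -1, -1, a);
        if (fi >= 0) { c.fil1 = fi; c.a1 = a; }
      }
      continue;
    }

    if (c.fil1 >= 0 && c.fil2 >= 0) {
      any = true;
      Filament &f1 = E.fils[c.fil1], &f2 = E.fils[c.fil2];
      double p1x, p1y, t1x, t1y, p2x, p2y, t2x, t2y; int s1, s2; double w1, w2;
      point_at(E, f1, c.a1, p1x, p1y, t1x, t1y, s1, w1);
      point_at(E, f2, c.a2, p2x, p2y, t2x, t2y, s2, w2);
      double ex = p2x - p1x, ey = p2y - p1y;
      double Fx = E.k_mot * 1e3 * ex, Fy = E.k_mot * 1e3 * ey;  // on head 1
      apply_at(f1, s1, w1, Fx, Fy);
      apply_at(f2, s2, w2, -Fx, -Fy);
      double fmag = std::hypot(Fx, Fy);
      // head 1
      bool e1 = (c.a1 <= 1e-9) || (c.a1 >= f1.len - 1e-9);
      double rate1 = (e1 ? E.r_detach_end : E.r_detach0) * std::exp(fmag / E.f0);
      if (R::unif_rand() < 1.0 - std::exp(-rate1 * E.dt)) c.fil1 = -1;
      else {
        double f_op = Fx * t1x + Fy * t1y;
        c.a1 = std::max(0.0, c.a1 - load_velocity(f_op, E.f0, E.v_m) * E.dt);
      }
      // head 2
      bool e2 = (c.a2 <= 1e-9) || (c.a2 >= f2.len - 1e-9);
      double rate2 = (e2 ? E.r_detach_end : E.r_detach0) * std::exp(fmag / E.f0);
      if (R::unif_rand() < 1.0 - std::exp(-rate2 * E.dt)) c.fil2 = -1;
      else {
        double f_op = -Fx * t2x - Fy * t2y;
        c.a2 = std::max(0.0, c.a2 - load_velocity(f_op, E.f0, E.v_m) * E.dt);
      }
      if (c.fil1 < 0 && c.fil2 >= 0) { std::swap(c.fil1, c.fil2); std::swap(c.a1, c.a2); }
      double qx, qy, qtx, qty; int qs; double qw;
      if (c.fil1 >= 0) {
        point_at(E, E.fils[c.fil1], c.a1, qx, qy, qtx, qty, qs, qw);
        c.x = qx; c.y = qy;
      }
      continue;
    }

    // exactly one head bound: ride it, walk unloaded, try to bind the other
    if (c.fil1 < 0) { std::swap(c.fil1, c.fil2); std::swap(c.a1, c.a2); }
    Filament &f1 = E.fils[c.fil1];
    double px, py, tx, ty; int s1; double w1;
    point_at(E, f1, c.a1, px, py, tx, ty, s1, w1);
    c.x = px; c.y = py;
    bool e1 = (c.a1 <= 1e-9) || (c.a1 >= f1.len - 1e-9);
    double rate = e1 ? E.r_detach_end : E.r_detach0;
    if (R::unif_rand() < 1.0 - std::exp(-rate * E.dt)) { c.fil1 = -1; continue; }
    c.a1 = std::max(0.0, c.a1 - E.v_m * E.dt);
    if (R::unif_rand() < p_att) {
      double a; int fi = find_attach(E, c.x, c.y, c.fil1, -1, a);
      if (fi >= 0) { c.fil2 = fi; c.a2 = a; }
    }
  }
}

void integrate(Engine &E) {
  int n_mtoc = (int)E.mx.size();
  std::vector<double> Fmx(n_mtoc, 0.0), Fmy(n_mtoc, 0.0);
  std::vector<double> Gm(n_mtoc, E.gamma_body);
  for (Filament &f : E.fils) {
    for (size_t i = 0; i < f.vx.size(); ++i) {
      Fmx[f.mtoc] += f.fx[i]; Fmy[f.mtoc] += f.fy[i];
    }
    Fmx[f.mtoc] += f.rig_fx; Fmy[f.mtoc] += f.rig_fy;
    Gm[f.mtoc] += E.gamma_v * (double)(f.vx.size());
    if (f.mtoc == 0) {
      double r = std::hypot(E.mx[0], E.my[0]);
      if (r > 0) {
        E.cum_conf_fr += (f.conf_fx * E.mx[0] + f.conf_fy * E.my[0]) / r;
        E.cum_motor_fr += (f.rig_fx * E.mx[0] + f.rig_fy * E.my[0]) / r;
      }
    }
  }
  // MTOC body confinement + thermal noise; rigid translation
  std::vector<double> bdx(n_mtoc, 0.0), bdy(n_mtoc, 0.0);
  for (int k = 0; k < n_mtoc; ++k) {
    double r = std::hypot(E.mx[k], E.my[k]);
    if (r > E.r_cell - E.mtoc_radius && r > 0.0) {
      double pen = r - (E.r_cell - E.mtoc_radius);
      Fmx[k] += -E.k_conf * pen * E.mx[k] / r;
      Fmy[k] += -E.k_conf * pen * E.my[k] / r;
    }
    double sd = (E.kBT > 0.0) ? std::sqrt(2.0 * E.kBT * E.dt / Gm[k]) : 0.0;
    double ddx = Fmx[k] * E.dt / Gm[k], ddy = Fmy[k] * E.dt / Gm[k];
    // stability cap on the rigid step (stiff springs would otherwise
    // overshoot when k_mot dt / Gamma approaches 1)
    double dn = std::hypot(ddx, ddy), dcap = 0.45 * E.seg;
    if (dn > dcap) { ddx *= dcap / dn; ddy *= dcap / dn; }
    if (sd > 0.0) { ddx += R::norm_rand() * sd; ddy += R::norm_rand() * sd; }
    E.mx[k] += ddx; E.my[k] += ddy;
    bdx[k] = ddx; bdy[k] = ddy;
  }
  // filament shape relaxation
  const double cap = 0.45 * E.seg;
  const double beta = 1.0 - std::exp(-E.kappa / (E.seg * E.seg * E.seg * E.gamma_v) * E.dt);
  const double vsd = (E.kBT > 0.0) ? std::sqrt(2.0 * E.kBT * E.dt / E.gamma_v) : 0.0;
  for (Filament &f : E.fils) {
    size_t nv = f.vx.size();
    // filaments translate rigidly with their MTOC; shape forces act on top
    for (size_t i = 0; i < nv; ++i) {
      f.vx[i] += bdx[f.mtoc]; f.vy[i] += bdy[f.mtoc];
    }
    for (size_t i = 1; i < nv; ++i) {
      double dx = f.fx[i] * E.dt / E.gamma_v;
      double dy = f.fy[i] * E.dt / E.gamma_v;
      if (vsd > 0.0) { dx += R::norm_rand() * vsd; dy += R::norm_rand() * vsd; }
      double n = std::hypot(dx, dy);
      if (n > cap) { dx *= cap / n; dy *= cap / n; }
      f.vx[i] += dx; f.vy[i] += dy;
    }
    // clamp the minus-end anchor to the (moved) MTOC rim
    f.vx[0] = E.mx[f.mtoc] + E.mtoc_radius * f.ax;
    f.vy[0] = E.my[f.mtoc] + E.mtoc_radius * f.ay;
    // follow-the-leader projection: exact contour length
    for (size_t i = 1; i < nv; ++i) {
      double dx = f.vx[i] - f.vx[i - 1], dy = f.vy[i] - f.vy[i - 1];
      double n = std::hypot(dx, dy);
      if (n < 1e-12) { dx = f.ax; dy = f.ay; n = 1.0; }
      double L = rest_len(E, f, (int)i - 1);
      f.vx[i] = f.vx[i - 1] + dx / n * L;
      f.vy[i] = f.vy[i - 1] + dy / n * L;
    }
    // overdamped straightening toward the previous segment direction
    for (size_t i = 2; i < nv; ++i) {
      double ux = f.vx[i - 1] - f.vx[i - 2], uy = f.vy[i - 1] - f.vy[i - 2];
      double un = std::hypot(ux, uy);
      if (un < 1e-12) continue;
      ux /= un; uy /= un;
      double dx = f.vx[i] - f.vx[i - 1], dy = f.vy[i] - f.vy[i - 1];
      double dn = std::hypot(dx, dy);
      if (dn < 1e-12) continue;
      double L = rest_len(E, f, (int)i - 1);  // exact contour preservation
      double bx = (1.0 - beta) * dx / dn + beta * ux;
      double by = (1.0 - beta) * dy / L + beta * uy;
      double bn = std::hypot(bx, by);
      if (bn < 1e-12) continue;
      f.vx[i] = f.vx[i - 1] + bx / bn * L;
      f.vy[i] = f.vy[i - 1] + by / bn * L;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List aster_run_cpp(int n_mtoc, int n_mt, double total_time, double dt,
                   double r_cell, double r_chr,
                   double eta, double kappa, double kBT,
                   double vg_c, double vs_c, double fcat_c, double fres_c,
                   double vg_s, double vs_s, double fcat_s, double fres_s,
                   bool di_gradient,
                   int n_mi, bool motor_gradient,
                   int n_mc,
                   double a_rhalf, double a_s,
                   double k_mot, double v_m, double f0,
                   double r_attach, double r_detach0, double r_detach_end,
                   double d_attach, double D_c,
                   double record_interval,
                   NumericVector mtoc_x0, NumericVector mtoc_y0,
                   double init_len) {
  Engine E;
  E.r_cell = r_cell; E.r_chr = r_chr; E.eta = eta; E.kappa = kappa; E.kBT = kBT;
  E.seg = 0.5; E.dt = dt;
  E.vg_c = vg_c; E.vs_c = vs_c; E.fcat_c = fcat_c; E.fres_c = fres_c;
  E.vg_s = vg_s; E.vs_s = vs_s; E.fcat_s = fcat_s; E.fres_s = fres_s;
  E.di_gradient = di_gradient;
  E.a_on = true; E.a_rhalf = a_rhalf; E.a_s = a_s;
  E.k_mot = k_mot; E.v_m = v_m; E.f0 = f0;
  E.r_attach = r_attach; E.r_detach0 = r_detach0; E.r_detach_end = r_detach_end;
  E.d_attach = d_attach; E.D_c = D_c;
  E.k_conf = 10.0;           // pN/um harmonic cortex, buckling-capped per filament
  E.mtoc_radius = 0.2;
  // cylinder-transverse drag per 0.5 um segment (MT diameter 25 nm);
  // Stokes drag for the MTOC body
  E.gamma_v = 4.0 * M_PI * eta * E.seg / (std::log(E.seg / 0.025) + 0.84);
  E.gamma_body = 6.0 * M_PI * eta * E.mtoc_radius;
  E.max_pair_imbalance = 0.0;
  E.bind_events = 0; E.cum_motor_fr = 0.0; E.cum_conf_fr = 0.0;

  // MTOC initial positions: uniform by area in the cytoplasmic annulus
  E.mx.resize(n_mtoc); E.my.resize(n_mtoc);
  for (int k = 0; k < n_mtoc; ++k) {
    if (mtoc_x0.size() > 0) { E.mx[k] = mtoc_x0[k]; E.my[k] = mtoc_y0[k]; }
    else {
      double u = R::unif_rand();
      double rr = std::sqrt(r_chr * r_chr + u * (r_cell * r_cell - r_chr * r_chr));
      double th = R::runif(0.0, 2.0 * M_PI);
      E.mx[k] = rr * std::cos(th); E.my[k] = rr * std::sin(th);
    }
  }
  // filaments: radial spokes at uniform angular spacing
  for (int k = 0; k < n_mtoc; ++k) {
    for (int j = 0; j < n_mt; ++j) {
      Filament f;
      f.mtoc = k; f.rig_fx = f.rig_fy = 0.0;
      double th = 2.0 * M_PI * j / n_mt;
      f.ax = std::cos(th); f.ay = std::sin(th);
      f.len = init_len;
      f.growing = true;
      int ns = std::max(1, (int)std::ceil(f.len / E.seg - 1e-12));
      double x0 = E.mx[k] + E.mtoc_radius * f.ax;
      double y0 = E.my[k] + E.mtoc_radius * f.ay;
      for (int i = 0; i <= ns; ++i) {
        double d = (i < ns) ? E.seg * i : f.len;
        f.vx.push_back(x0 + f.ax * d); f.vy.push_back(y0 + f.ay * d);
      }
      E.fils.push_back(std::move(f));
    }
  }
  // immobilized motors: uniform over the cell disk, or rejection-sampled
  // against the attractive field
  for (int i = 0; i < n_mi; ++i) {
    double x, y;
    for (;;) {
      double u = R::unif_rand();
      double rr = r_cell * std::sqrt(u);
      double th = R::runif(0.0, 2.0 * M_PI);
      x = rr * std::cos(th); y = rr * std::sin(th);
      if (!motor_gradient) break;
      if (R::unif_rand() < phi_a_at(E, x, y)) break;
    }
    Motor m; m.x = x; m.y = y; m.fil = -1; m.a = 0.0;
    E.motors.push_back(m);
  }
  // diffusible complexes start in the cytoplasmic annulus
  for (int i = 0; i < n_mc; ++i) {
    double u = R::unif_rand();
    double rr = std::sqrt(r_chr * r_chr + u * (r_cell * r_cell - r_chr * r_chr));
    double th = R::runif(0.0, 2.0 * M_PI);
    Complex c; c.x = rr * std::cos(th); c.y = rr * std::sin(th);
    c.fil1 = c.fil2 = -1; c.a1 = c.a2 = 0.0;
    E.cplx.push_back(c);
  }

  E.cell_sz = 0.5;
  E.ncell = std::max(1, (int)std::ceil(2.0 * r_cell / E.cell_sz));
  E.grid.resize((size_t)E.ncell * E.ncell);

  const int n_steps = (int)std::lround(total_time / dt);
  const int rec_every = std::max(1, (int)std::lround(record_interval / dt));
  int n_rec = n_steps / rec_every + 1;
  NumericMatrix out_x(n_rec, n_mtoc), out_y(n_rec, n_mtoc);
  NumericVector out_t(n_rec);
  int rec = 0;
  for (int k = 0; k < n_mtoc; ++k) { out_x(0, k) = E.mx[k]; out_y(0, k) = E.my[k]; }
  out_t[0] = 0.0; rec = 1;

  std::vector<double> mean_len_acc; mean_len_acc.reserve(n_rec);
  NumericVector rec_bound(n_rec), rec_force(n_rec);
  bool any_pair = false;

  for (int step = 1; step <= n_steps; ++step) {
    di_step_engine(E);
    rebuild_grid(E);
    confinement_forces(E);
    if (!E.motors.empty()) motor_step(E);
    if (!E.cplx.empty()) { bool any; complex_step(E, any); any_pair = any_pair || any; }
    integrate(E);
    if (step % rec_every == 0 && rec < n_rec) {
      int nb = 0;
      for (const Motor &m : E.motors) if (m.fil >= 0) ++nb;
      rec_bound[rec] = nb;
      double fx0 = 0, fy0 = 0;
      for (const Filament &f : E.fils) if (f.mtoc == 0) {
        fx0 += f.rig_fx; fy0 += f.rig_fy;
        for (size_t i = 0; i < f.vx.size(); ++i) { fx0 += f.fx[i]; fy0 += f.fy[i]; }
      }
      rec_force[rec] = std::hypot(fx0, fy0);
      for (int k = 0; k < n_mtoc; ++k) { out_x(rec, k) = E.mx[k]; out_y(rec, k) = E.my[k]; }
      out_t[rec] = step * dt;
      double s = 0.0;
      for (const Filament &f : E.fils) s += f.len;
      mean_len_acc.push_back(E.fils.empty() ? 0.0 : s / (double)E.fils.size());
      ++rec;
    }
  }

  int bound_motors = 0;
  for (const Motor &m : E.motors) if (m.fil >= 0) ++bound_motors;
  NumericMatrix anchors(E.motors.size(), 2);
  for (size_t i = 0; i < E.motors.size(); ++i) {
    anchors(i, 0) = E.motors[i].x; anchors(i, 1) = E.motors[i].y;
  }

  return List::create(
    _["t"] = out_t, _["x"] = out_x, _["y"] = out_y,
    _["mean_filament_length"] = wrap(mean_len_acc),
    _["bound_motors_final"] = bound_motors,
    _["any_crosslink"] = any_pair,
    _["max_pair_imbalance"] = E.max_pair_imbalance,
    _["bind_events"] = (double)E.bind_events,
    _["motor_anchors"] = anchors,
    _["rec_bound"] = rec_bound, _["rec_force"] = rec_force,
    _["mean_motor_fr"] = E.cum_motor_fr / (double)n_steps,
    _["mean_conf_fr"] = E.cum_conf_fr / (double)n_steps);
}

// minimal single-motor pulling test: one MTOC at the origin with one
// filament along +x (dynamic instability frozen), one motor anchor at
// (ax, ay); returns the MTOC x-trajectory. Used to verify that an anchored
// minus-end-directed motor translates the aster toward its anchor.
// [[Rcpp::export]]
NumericVector motor_pull_debug_cpp(double ax, double ay, double total_time,
                                   double dt, double kBT, double f0) {
  Engine E;
  E.r_cell = 40; E.r_chr = 10; E.eta = 0.05; E.kappa = 20; E.kBT = kBT;
  E.seg = 0.5; E.dt = dt;
  E.vg_c = 0; E.vs_c = 0; E.fcat_c = 0; E.fres_c = 0;
  E.vg_s = 0; E.vs_s = 0; E.fcat_s = 0; E.fres_s = 0;
  E.di_gradient = false; E.a_on = true; E.a_rhalf = 10; E.a_s = 1;
  E.k_mot = 0.1; E.v_m = 2; E.f0 = f0;
  E.r_attach = 1e6; E.r_detach0 = 0; E.r_detach_end = 0;
  E.d_attach = 0.05; E.D_c = 0;
  E.k_conf = 10; E.mtoc_radius = 0.2;
  E.gamma_v = 4.0 * M_PI * E.eta * E.seg / (std::log(E.seg / 0.025) + 0.84);
  E.gamma_body = 6.0 * M_PI * E.eta * E.mtoc_radius;
  E.max_pair_imbalance = 0; E.bind_events = 0;
  E.cum_motor_fr = 0; E.cum_conf_fr = 0;
  E.mx.assign(1, 0.0); E.my.assign(1, 0.0);
  Filament f; f.mtoc = 0; f.ax = 1; f.ay = 0; f.len = 3.0; f.growing = true;
  f.rig_fx = f.rig_fy = 0.0;
  for (int i = 0; i <= 6; ++i) {
    f.vx.push_back(0.2 + 0.5 * i); f.vy.push_back(0.0);
  }
  E.fils.push_back(f);
  Motor m; m.x = ax; m.y = ay; m.fil = -1; m.a = 0; E.motors.push_back(m);
  E.cell_sz = 0.5; E.ncell = 160; E.grid.resize((size_t)E.ncell * E.ncell);
  int n = (int)std::lround(total_time / dt);
  NumericVector out(n + 1); out[0] = 0;
  NumericVector dbg_a(n + 1), dbg_f(n + 1);
  for (int s = 1; s <= n; ++s) {
    for (Filament &ff : E.fils) {
      ff.fx.assign(ff.vx.size(), 0.0); ff.fy.assign(ff.vy.size(), 0.0);
      ff.conf_fx = 0; ff.conf_fy = 0; ff.rig_fx = 0; ff.rig_fy = 0;
    }
    rebuild_grid(E);
    confinement_forces(E);
    motor_step(E);
    integrate(E);
    out[s] = E.mx[0];
    dbg_a[s] = E.motors[0].fil >= 0 ? E.motors[0].a : -1;
    dbg_f[s] = std::hypot(E.fils[0].rig_fx, E.fils[0].rig_fy);
  }
  out.attr("a") = dbg_a; out.attr("f") = dbg_f;
  return out;
}

// single-filament dynamic-instability simulation (length vs time), used to
// cross-check the bounded-regime closed-form mean length
// [[Rcpp::export]]
NumericVector di_simulate_cpp(double vg, double vs, double fcat, double fres,
                              double total_time, double dt, double init_len) {
  int n = (int)std::lround(total_time / dt);
  NumericVector len(n + 1);
  double L = init_len; bool growing = true;
  len[0] = L;
  const double p_cat = 1.0 - std::exp(-fcat * dt);
  const double p_res = 1.0 - std::exp(-fres * dt);
  for (int i = 1; i <= n; ++i) {
    if (growing) {
      L += vg * dt;
      if (R::unif_rand() < p_cat) growing = false;
    } else {
      L -= vs * dt;
      if (L <= 0.0) { L = 0.0; growing = true; }
      else if (R::unif_rand() < p_res) growing = true;
    }
    len[i] = L;
  }
  return len;
}
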