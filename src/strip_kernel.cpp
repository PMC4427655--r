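// Equilibrium kernel for the mitral-valve strip model: nodal force
// residual of two elastic leaflet cables under a follower pressure
// load with tension-only (optionally wrapping) chordae and smoothed
// penalty contact, plus a finite-difference Jacobian and a dynamic-
// relaxation driver.  Mirrors the reference R implementation
// (.strip_residual_r); a unit test asserts the two agree.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Law {
  double A, B;
  bool tension_only;
};

// leaflet cable stress: exponential in tension, linear initial-tangent
// branch in compression
inline double cable_stress(const Law &law, double eps) {
  double s = law.A * (std::exp(law.B * std::max(eps, 0.0)) - 1.0);
  if (!law.tension_only) s += law.A * law.B * std::min(eps, 0.0);
  return s;
}

// chordae stress: tension-only with a C1 cubic blend on [0, eps_s]
inline double chord_stress(const Law &law, double eps) {
  const double eps_s = 0.01;
  if (eps <= 0) return 0.0;
  if (eps >= eps_s) return law.A * (std::exp(law.B * eps) - 1.0);
  double ss = law.A * (std::exp(law.B * eps_s) - 1.0);
  double ds = law.A * law.B * std::exp(law.B * eps_s);
  double tt = eps / eps_s;
  return (3 * tt * tt - 2 * tt * tt * tt) * ss +
         (tt * tt * tt - tt * tt) * ds * eps_s;
}

// C1-smoothed penalty force magnitude
inline double pen_force(double kpen, double pen, double delta) {
  if (pen >= delta) return kpen * pen;
  if (pen > -delta) {
    double b = pen + delta;
    return kpen * b * b / (4 * delta);
  }
  return 0.0;
}

struct Chord {
  int cable;      // 0 = anterior, 1 = posterior
  int node;       // 1-based free-node index on its cable
  Law law;
  double area, rest, papx, papz;
};

struct Problem {
  int na, np;
  double hax, haz, hpx, hpz;
  std::vector<double> l0a, l0p, wta;
  double acs;
  Law law;
  double dp, w, kbend, d0, kpen, blend, gap_tol;
  std::vector<Chord> chordae;
  bool has_elem;
  double ex, ez, er;
};

Problem parse_problem(const List &pr) {
  Problem p;
  p.na = as<int>(pr["na"]);
  p.np = as<int>(pr["np"]);
  NumericVector ha = pr["hinge_a"], hp = pr["hinge_p"];
  p.hax = ha[0]; p.haz = ha[1]; p.hpx = hp[0]; p.hpz = hp[1];
  p.l0a = as<std::vector<double>>(pr["l0a"]);
  p.l0p = as<std::vector<double>>(pr["l0p"]);
  p.wta = as<std::vector<double>>(pr["wta"]);
  p.acs = as<double>(pr["acs"]);
  List law = pr["law"];
  p.law.A = as<double>(law["A"]);
  p.law.B = as<double>(law["B"]);
  p.law.tension_only = as<bool>(law["tension_only"]);
  p.dp = as<double>(pr["dp"]);
  p.w = as<double>(pr["w"]);
  p.kbend = as<double>(pr["kbend"]);
  p.d0 = as<double>(pr["d0"]);
  p.kpen = as<double>(pr["kpen"]);
  p.blend = as<double>(pr["blend"]);
  p.gap_tol = as<double>(pr["gap_tol"]);
  List ch = pr["chordae"];
  for (int k = 0; k < ch.size(); ++k) {
    List c = ch[k];
    Chord cd;
    std::string cable = as<std::string>(c["cable"]);
    cd.cable = (cable == "a") ? 0 : 1;
    cd.node = as<int>(c["node"]);
    List claw = c["law"];
    cd.law.A = as<double>(claw["A"]);
    cd.law.B = as<double>(claw["B"]);
    cd.law.tension_only = as<bool>(claw["tension_only"]);
    cd.area = as<double>(c["area"]);
    cd.rest = as<double>(c["rest"]);
    NumericVector pp = c["pap"];
    cd.papx = pp[0]; cd.papz = pp[1];
    p.chordae.push_back(cd);
  }
  p.has_elem = !Rf_isNull(pr["elem"]);
  if (p.has_elem) {
    List el = pr["elem"];
    NumericVector cc = el["c"];
    p.ex = cc[0]; p.ez = cc[1];
    p.er = as<double>(el["r"]);
  }
  return p;
}

struct EvalOut {
  std::vector<double> R;
  std::vector<double> chord_forces;
  double max_pen, tip_sep, mindist;
  std::vector<int> contact_node_a;
};

// chordae path with frictionless wrap around the element circle
void chord_path(const Problem &p, double px, double pz, double x, double z,
                double &len, double &dirx, double &dirz) {
  double vx = x - px, vz = z - pz;
  double straight = std::sqrt(vx * vx + vz * vz);
  len = straight; dirx = vx / straight; dirz = vz / straight;
  if (!p.has_elem) return;
  double cx = p.ex, cz = p.ez, r = p.er;
  double vv = vx * vx + vz * vz;
  double tt = ((cx - px) * vx + (cz - pz) * vz) / vv;
  if (tt <= 0 || tt >= 1) return;
  double nx = px + tt * vx - cx, nz = pz + tt * vz - cz;
  if (std::sqrt(nx * nx + nz * nz) >= r) return;
  double d1 = std::hypot(px - cx, pz - cz);
  double d2 = std::hypot(x - cx, z - cz);
  if (d1 <= r || d2 <= r) return;
  double best_len = -1, best_t2x = 0, best_t2z = 0;
  for (int si = 0; si < 2; ++si) {
    double s = si == 0 ? 1.0 : -1.0;
    // tangent point from pap with rotation +s*g1, from x with -s*g2
    double g1 = std::acos(std::min(1.0, r / d1));
    double u1x = (px - cx) / d1, u1z = (pz - cz) / d1;
    double t1x = cx + r * (std::cos(s * g1) * u1x - std::sin(s * g1) * u1z);
    double t1z = cz + r * (std::sin(s * g1) * u1x + std::cos(s * g1) * u1z);
    double g2 = std::acos(std::min(1.0, r / d2));
    double u2x = (x - cx) / d2, u2z = (z - cz) / d2;
    double t2x = cx + r * (std::cos(-s * g2) * u2x - std::sin(-s * g2) * u2z);
    double t2z = cz + r * (std::sin(-s * g2) * u2x + std::cos(-s * g2) * u2z);
    double a1 = std::atan2(t1z - cz, t1x - cx);
    double a2 = std::atan2(t2z - cz, t2x - cx);
    double da = a2 - a1 + M_PI;      // bounded: |a2 - a1| <= 2*pi
    while (da < 0) da += 2 * M_PI;
    while (da >= 2 * M_PI) da -= 2 * M_PI;
    double darc = std::fabs(da - M_PI);
    double lw = std::sqrt(std::max(d1 * d1 - r * r, 0.0)) +
                std::sqrt(std::max(d2 * d2 - r * r, 0.0)) + r * darc;
    if (best_len < 0 || lw < best_len) {
      best_len = lw; best_t2x = t2x; best_t2z = t2z;
    }
  }
  if (best_len <= straight) return;
  len = best_len;
  double dx = x - best_t2x, dz = z - best_t2z;
  double dn = std::sqrt(dx * dx + dz * dz);
  dirx = dx / dn; dirz = dz / dn;
}

// node-to-segment distance
inline void seg_dist(double sx, double sz, double m1x, double m1z,
                     double m2x, double m2z, double &t, double &d,
                     double &dx, double &dz) {
  double vx = m2x - m1x, vz = m2z - m1z;
  double vv = vx * vx + vz * vz;
  t = ((sx - m1x) * vx + (sz - m1z) * vz) / vv;
  if (t < 0) t = 0; else if (t > 1) t = 1;
  double cx = m1x + t * vx, cz = m1z + t * vz;
  dx = sx - cx; dz = sz - cz;
  d = std::sqrt(dx * dx + dz * dz);
}

void eval_residual(const Problem &p, const double *u, EvalOut &out) {
  const int na = p.na, np = p.np;
  const double *ax = u, *az = u + na, *px = u + 2 * na, *pz = u + 2 * na + np;
  std::vector<double> rxa(na, 0.0), rza(na, 0.0), rxp(np, 0.0), rzp(np, 0.0);

  // cables: elastic + bending + follower pressure
  auto do_cable = [&](double hx, double hz, const double *x, const double *z,
                      const std::vector<double> &l0, double sgn,
                      std::vector<double> &rx, std::vector<double> &rz) {
    int n = (int)l0.size();
    std::vector<double> X(n + 1), Z(n + 1);
    X[0] = hx; Z[0] = hz;
    for (int i = 0; i < n; ++i) { X[i + 1] = x[i]; Z[i + 1] = z[i]; }
    std::vector<double> fx(n), fz(n);
    for (int i = 0; i < n; ++i) {
      double dx = X[i + 1] - X[i], dz = Z[i + 1] - Z[i];
      double l = std::sqrt(dx * dx + dz * dz);
      double eps = std::log(l / l0[i]);
      double f = p.acs * cable_stress(p.law, eps) * (l0[i] / l);
      fx[i] = f * dx / l; fz[i] = f * dz / l;
    }
    for (int i = 0; i < n; ++i) {
      rx[i] += fx[i] - (i + 1 < n ? fx[i + 1] : 0.0);
      rz[i] += fz[i] - (i + 1 < n ? fz[i + 1] : 0.0);
    }
    // bending: discrete Laplacian over coordinate positions 1..n-1
    for (int i = 1; i < n; ++i) {
      double vbx = X[i - 1] - 2 * X[i] + X[i + 1];
      double vbz = Z[i - 1] - 2 * Z[i] + Z[i + 1];
      int idx = i - 1;               // free-node index of X[i] is i-1+1=i... (1-based)
      // free nodes are X[1..n] -> rx[0..n-1]; center X[i] -> rx[i-1]
      if (idx - 1 >= 0) { rx[idx - 1] += p.kbend * vbx;
                          rz[idx - 1] += p.kbend * vbz; }
      rx[idx] += -2 * p.kbend * vbx;
      rz[idx] += -2 * p.kbend * vbz;
      rx[idx + 1] += p.kbend * vbx;
      rz[idx + 1] += p.kbend * vbz;
    }
    // follower pressure
    double q = p.dp * p.w;
    for (int j = 1; j <= n; ++j) {
      double cx, cz;
      if (j < n) { cx = X[j + 1] - X[j - 1]; cz = Z[j + 1] - Z[j - 1]; }
      else { cx = X[n] - X[n - 1]; cz = Z[n] - Z[n - 1]; }
      rx[j - 1] -= sgn * q / 2 * (-cz);
      rz[j - 1] -= sgn * q / 2 * (cx);
    }
  };
  do_cable(p.hax, p.haz, ax, az, p.l0a, +1.0, rxa, rza);
  do_cable(p.hpx, p.hpz, px, pz, p.l0p, -1.0, rxp, rzp);

  // chordae
  out.chord_forces.assign(p.chordae.size(), 0.0);
  for (size_t k = 0; k < p.chordae.size(); ++k) {
    const Chord &c = p.chordae[k];
    double xx = (c.cable == 0) ? ax[c.node - 1] : px[c.node - 1];
    double zz = (c.cable == 0) ? az[c.node - 1] : pz[c.node - 1];
    double len, dirx, dirz;
    chord_path(p, c.papx, c.papz, xx, zz, len, dirx, dirz);
    double eps = std::log(len / c.rest);
    double f = c.area * chord_stress(c.law, eps) * (c.rest / len);
    out.chord_forces[k] = f;
    if (c.cable == 0) {
      rxa[c.node - 1] += f * dirx; rza[c.node - 1] += f * dirz;
    } else {
      rxp[c.node - 1] += f * dirx; rzp[c.node - 1] += f * dirz;
    }
  }

  // leaflet-leaflet node-to-segment contact, both directions
  std::vector<double> AX(na + 1), AZ(na + 1), PX(np + 1), PZ(np + 1);
  AX[0] = p.hax; AZ[0] = p.haz; PX[0] = p.hpx; PZ[0] = p.hpz;
  for (int i = 0; i < na; ++i) { AX[i + 1] = ax[i]; AZ[i + 1] = az[i]; }
  for (int i = 0; i < np; ++i) { PX[i + 1] = px[i]; PZ[i + 1] = pz[i]; }
  out.max_pen = 0.0;
  out.mindist = R_PosInf;
  out.contact_node_a.assign(na, 0);
  for (int dir = 0; dir < 2; ++dir) {
    int nslave = dir == 0 ? na : np;
    int nseg = dir == 0 ? np : na;
    for (int seg = 0; seg < nseg; ++seg) {
      double m1x = dir == 0 ? PX[seg] : AX[seg];
      double m1z = dir == 0 ? PZ[seg] : AZ[seg];
      double m2x = dir == 0 ? PX[seg + 1] : AX[seg + 1];
      double m2z = dir == 0 ? PZ[seg + 1] : AZ[seg + 1];
      for (int i = 0; i < nslave; ++i) {
        double sx = dir == 0 ? ax[i] : px[i];
        double sz = dir == 0 ? az[i] : pz[i];
        double t, d, dx, dz;
        seg_dist(sx, sz, m1x, m1z, m2x, m2z, t, d, dx, dz);
        if (d < out.mindist) out.mindist = d;
        if (dir == 0 && d <= p.d0 + p.gap_tol) out.contact_node_a[i] = 1;
        double pen = p.d0 - d;
        if (pen <= -p.blend || d <= 1e-9) continue;
        if (pen > out.max_pen) out.max_pen = pen;
        double fmag = pen_force(p.kpen, pen, p.blend) / d;
        double fxv = fmag * dx, fzv = fmag * dz;
        if (dir == 0) {
          rxa[i] -= fxv; rza[i] -= fzv;
          if (seg >= 1) { rxp[seg - 1] += (1 - t) * fxv;
                          rzp[seg - 1] += (1 - t) * fzv; }
          rxp[seg] += t * fxv; rzp[seg] += t * fzv;
        } else {
          rxp[i] -= fxv; rzp[i] -= fzv;
          if (seg >= 1) { rxa[seg - 1] += (1 - t) * fxv;
                          rza[seg - 1] += (1 - t) * fzv; }
          rxa[seg] += t * fxv; rza[seg] += t * fzv;
        }
      }
    }
  }
  // free-edge separation: tip nodes vs the other cable
  double tip_sep = R_PosInf;
  for (int seg = 0; seg < np; ++seg) {
    double t, d, dx, dz;
    seg_dist(ax[na - 1], az[na - 1], PX[seg], PZ[seg], PX[seg + 1],
             PZ[seg + 1], t, d, dx, dz);
    if (d < tip_sep) tip_sep = d;
  }
  for (int seg = 0; seg < na; ++seg) {
    double t, d, dx, dz;
    seg_dist(px[np - 1], pz[np - 1], AX[seg], AZ[seg], AX[seg + 1],
             AZ[seg + 1], t, d, dx, dz);
    if (d < tip_sep) tip_sep = d;
  }
  out.tip_sep = tip_sep;

  // sub-valvular element vs posterior leaflet nodes
  if (p.has_elem) {
    double clear = p.er + p.d0 / 2;
    for (int i = 0; i < np; ++i) {
      double exv = px[i] - p.ex, ezv = pz[i] - p.ez;
      double ed = std::sqrt(exv * exv + ezv * ezv);
      double epen = clear - ed;
      if (epen <= -p.blend || ed <= 1e-9) continue;
      if (epen > out.max_pen) out.max_pen = epen;
      double coef = -pen_force(p.kpen, epen, p.blend) / ed;
      rxp[i] += coef * exv; rzp[i] += coef * ezv;
    }
  }

  out.R.resize(2 * (na + np));
  for (int i = 0; i < na; ++i) { out.R[i] = rxa[i]; out.R[na + i] = rza[i]; }
  for (int i = 0; i < np; ++i) {
    out.R[2 * na + i] = rxp[i];
    out.R[2 * na + np + i] = rzp[i];
  }
}

List out_to_list(const EvalOut &out) {
  LogicalVector ca(out.contact_node_a.size());
  for (size_t i = 0; i < out.contact_node_a.size(); ++i)
    ca[i] = out.contact_node_a[i] != 0;
  return List::create(
    _["R"] = wrap(out.R),
    _["chord_forces"] = wrap(out.chord_forces),
    _["max_pen"] = out.max_pen,
    _["contact_node_a"] = ca,
    _["tip_sep"] = out.tip_sep,
    _["mindist"] = out.mindist);
}

}  // namespace

// [[Rcpp::export(name = ".cpp_strip_residual")]]
List cpp_strip_residual(List pr, NumericVector u) {
  Problem p = parse_problem(pr);
  EvalOut out;
  eval_residual(p, u.begin(), out);
  return out_to_list(out);
}

// [[Rcpp::export(name = ".cpp_strip_jacobian")]]
NumericMatrix cpp_strip_jacobian(List pr, NumericVector u) {
  Problem p = parse_problem(pr);
  int n = u.size();
  EvalOut base;
  eval_residual(p, u.begin(), base);
  NumericMatrix J(n, n);
  std::vector<double> up(u.begin(), u.end());
  EvalOut pert;
  for (int j = 0; j < n; ++j) {
    double h = 1e-6 * (1.0 + std::fabs(u[j]));
    double keep = up[j];
    up[j] = keep + h;
    eval_residual(p, up.data(), pert);
    for (int i = 0; i < n; ++i) J(i, j) = (pert.R[i] - base.R[i]) / h;
    up[j] = keep;
  }
  return J;
}

// [[Rcpp::export(name = ".cpp_strip_dr")]]
NumericVector cpp_strip_dr(List pr, NumericVector u0, int max_steps,
                           double rtol, double scale) {
  Problem p = parse_problem(pr);
  int n = u0.size();
  std::vector<double> u(u0.begin(), u0.end());
  EvalOut ev;
  eval_residual(p, u.data(), ev);
  // stability step from the stiffest FD diagonal
  double kmax = 1.0;
  for (int j = 0; j < n; ++j) {
    double h = 1e-5 * (1.0 + std::fabs(u[j]));
    double keep = u[j];
    u[j] = keep + h;
    EvalOut pert;
    eval_residual(p, u.data(), pert);
    u[j] = keep;
    double k = std::fabs((pert.R[j] - ev.R[j]) / h);
    if (k > kmax) kmax = k;
  }
  double dt = 0.7 * std::sqrt(2.0 / kmax);
  std::vector<double> v(n, 0.0), best_u(u);
  double ke_prev = 0.0, best_r = 0.0;
  for (int i = 0; i < n; ++i)
    best_r = std::max(best_r, std::fabs(ev.R[i]));
  for (int step = 0; step < max_steps; ++step) {
    double ke = 0.0;
    for (int i = 0; i < n; ++i) {
      v[i] -= dt * ev.R[i];
      ke += v[i] * v[i];
    }
    if (ke < ke_prev) std::fill(v.begin(), v.end(), 0.0);
    ke_prev = ke;
    for (int i = 0; i < n; ++i) u[i] += dt * v[i];
    eval_residual(p, u.data(), ev);
    double r = 0.0;
    bool ok = true;
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(ev.R[i])) { ok = false; break; }
      r = std::max(r, std::fabs(ev.R[i]));
    }
    if (!ok) {
      u = best_u;
      std::fill(v.begin(), v.end(), 0.0);
      dt /= 2;
      eval_residual(p, u.data(), ev);
      continue;
    }
    if (r < best_r) { best_r = r; best_u = u; }
    if (r < rtol * scale) break;
  }
  return wrap(best_u);
}
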