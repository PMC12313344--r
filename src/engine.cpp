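// Brownian-dynamics kernel for SMC loop extrusion on a bead-spring DNA chain.
// All arithmetic is in reduced units: sigma = epsilon (k_BT) = tau_B = 1.
#include <Rcpp.h>
#include <vector>
#include <stdexcept>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

static const double H_FD = 1e-5;  // central-difference step for angular-term forces

// ---------------------------------------------------------------- parameters

struct FFParams {
  double eps = 1.0, sigma = 1.0;
  double rc2 = std::pow(2.0, 1.0 / 3.0);  // (2^{1/6} sigma)^2
  double fene_k = 30.0, fene_R0 = 1.5;
  double kp = 5.0;  // bending prefactor k_BT l_p / sigma
  double smc_k = 5.0, smc_r0 = 1.6;
  double quad = 5.0;  // dihedral quadratic prefactor
  bool wca_on = true, bonds_on = true, bend_on = true;
};

struct Field {
  bool slab = false;
  double slab_gap = 3.0, wall_k = 100.0, wall_margin = 0.5;
  bool tether = false;
  double tether_f = 0.0;  // pulls end beads apart along x
};

// variants: 0 two_spring_asym, 1 one_spring, 2 barycentre_axis,
//           3 dihedral_asym, 4 dihedral_sym
struct SMC {
  bool loaded = false;
  int a = -1, h = -1;  // 0-based anchor / head bead
  int variant = 0;
  double gamma_deg = 60.0, rmin = 1.0, rmax = 4.0;
  int jump_cap = 5;
  bool cone_ge = true;  // capture cone: cos(angle) >= cos(gamma/2)

  inline int s() const { return h > a ? 1 : -1; }
  inline int a_in() const { return a + s(); }    // loop-side neighbour of anchor
  inline int h_in() const { return h - s(); }    // loop-side neighbour of head
  inline int a_out() const { return a - s(); }
  inline int h_out() const { return h + s(); }
  inline bool two_springs() const {
    return variant == 0 || variant == 2 || variant == 4;
  }
  inline bool angular() const { return variant == 3 || variant == 4; }
};

static FFParams params_from_list(const List &p) {
  FFParams q;
  if (p.containsElementNamed("wca_epsilon")) q.eps = as<double>(p["wca_epsilon"]);
  if (p.containsElementNamed("wca_sigma")) q.sigma = as<double>(p["wca_sigma"]);
  q.rc2 = std::pow(2.0, 1.0 / 3.0) * q.sigma * q.sigma;
  if (p.containsElementNamed("fene_k")) q.fene_k = as<double>(p["fene_k"]);
  if (p.containsElementNamed("fene_R0")) q.fene_R0 = as<double>(p["fene_R0"]);
  if (p.containsElementNamed("kp_prefactor")) q.kp = as<double>(p["kp_prefactor"]);
  if (p.containsElementNamed("smc_k")) q.smc_k = as<double>(p["smc_k"]);
  if (p.containsElementNamed("smc_r0")) q.smc_r0 = as<double>(p["smc_r0"]);
  if (p.containsElementNamed("quad_prefactor")) q.quad = as<double>(p["quad_prefactor"]);
  if (p.containsElementNamed("wca_on")) q.wca_on = as<bool>(p["wca_on"]);
  if (p.containsElementNamed("bonds_on")) q.bonds_on = as<bool>(p["bonds_on"]);
  if (p.containsElementNamed("bend_on")) q.bend_on = as<bool>(p["bend_on"]);
  return q;
}

static Field field_from_list(const Nullable<List> &f_) {
  Field f;
  if (f_.isNull()) return f;
  List fl(f_);
  std::string mode = as<std::string>(fl["mode"]);
  f.slab = (mode == "slab" || mode == "slab+tether");
  f.tether = (mode == "tether" || mode == "slab+tether");
  if (fl.containsElementNamed("slab_gap")) f.slab_gap = as<double>(fl["slab_gap"]);
  if (fl.containsElementNamed("tether_force")) f.tether_f = as<double>(fl["tether_force"]);
  if (fl.containsElementNamed("wall_k")) f.wall_k = as<double>(fl["wall_k"]);
  return f;
}

static SMC smc_from_list(const Nullable<List> &s_) {
  SMC s;
  if (s_.isNull()) return s;
  List sl(s_);
  s.loaded = true;
  s.a = as<int>(sl["anchor"]) - 1;  // R side is 1-based
  s.h = as<int>(sl["head"]) - 1;
  if (sl.containsElementNamed("variant_id")) s.variant = as<int>(sl["variant_id"]);
  if (sl.containsElementNamed("gamma")) s.gamma_deg = as<double>(sl["gamma"]);
  if (sl.containsElementNamed("shell_min")) s.rmin = as<double>(sl["shell_min"]);
  if (sl.containsElementNamed("shell_max")) s.rmax = as<double>(sl["shell_max"]);
  if (sl.containsElementNamed("jump_cap")) s.jump_cap = as<int>(sl["jump_cap"]);
  if (sl.containsElementNamed("cone_ge")) s.cone_ge = as<bool>(sl["cone_ge"]);
  return s;
}

// ---------------------------------------------------------------- geometry

static inline double dot3(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double *a, const double *b, double *c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double norm3(const double *a) { return std::sqrt(dot3(a, a)); }

// ------------------------------------------------------- SMC angular energy

// Deviation-from-orthogonality penalty: kp * (1 - sin(theta)) where theta is
// the angle between segment vector b and the capture axis u. Minimum when the
// segment is orthogonal to the axis (theta = pi/2), as for the torsion-variant
// boundary segments.
static inline double u_orth(const double *b, const double *u, double kp) {
  double c[3];
  cross3(b, u, c);
  double nb = norm3(b), nu = norm3(u);
  if (nb < 1e-12 || nu < 1e-12) return 0.0;
  double sint = norm3(c) / (nb * nu);
  if (sint > 1.0) sint = 1.0;
  return kp * (1.0 - sint);
}

// Quadratic dihedral penalty between the projections of b1 and b2 on the
// plane orthogonal to the (unit) axis u; minimum at phi = 0.
static inline double u_dihedral(const double *b1, const double *b2,
                                const double *u, double quad) {
  double p1[3], p2[3];
  double d1 = dot3(b1, u), d2 = dot3(b2, u);
  for (int k = 0; k < 3; ++k) {
    p1[k] = b1[k] - d1 * u[k];
    p2[k] = b2[k] - d2 * u[k];
  }
  if (norm3(p1) < 1e-9 || norm3(p2) < 1e-9) return 0.0;  // degenerate frame
  double cr[3];
  cross3(p1, p2, cr);
  double phi = std::atan2(dot3(u, cr), dot3(p1, p2));
  return quad * phi * phi;
}

// Angular (torsion-variant) energy bundle, Eqs. of the asymmetric/symmetric
// dihedral models. Involves beads a, h and their chain neighbours.
static double smc_angular_energy(const double *x, int N, const SMC &smc,
                                 const FFParams &p) {
  if (!smc.angular()) return 0.0;
  const double *ra = x + 3 * smc.a;
  const double *rh = x + 3 * smc.h;
  double u[3] = {rh[0] - ra[0], rh[1] - ra[1], rh[2] - ra[2]};
  double nu = norm3(u);
  if (nu < 1e-9) return 0.0;
  for (int k = 0; k < 3; ++k) u[k] /= nu;

  int ai = smc.a_in(), hi = smc.h_in();
  double ba[3], bh[3];
  for (int k = 0; k < 3; ++k) {
    ba[k] = x[3 * ai + k] - ra[k];
    bh[k] = x[3 * hi + k] - rh[k];
  }
  double e = u_orth(ba, u, p.kp) + u_orth(bh, u, p.kp) +
             u_dihedral(bh, ba, u, p.quad);
  if (smc.variant == 4) {
    int ao = smc.a_out(), ho = smc.h_out();
    if (ao >= 0 && ao < N && ho >= 0 && ho < N) {
      double bao[3], bho[3];
      for (int k = 0; k < 3; ++k) {
        bao[k] = x[3 * ao + k] - ra[k];
        bho[k] = x[3 * ho + k] - rh[k];
      }
      e += u_orth(bao, u, p.kp) + u_orth(bho, u, p.kp) +
           u_dihedral(bho, bao, u, p.quad);
    }
  }
  return e;
}

// ---------------------------------------------------------------- neighbours

struct NeighborList {
  std::vector<int> pairs;  // flattened (i, j), j > i + 1
  std::vector<double> ref;
  double rlist, skin = 0.4;

  void build(const double *x, int N, double rc) {
    rlist = rc + skin;
    double rl2 = rlist * rlist;
    pairs.clear();
    for (int i = 0; i < N; ++i)
      for (int j = i + 2; j < N; ++j) {
        double dx = x[3 * i] - x[3 * j];
        double dy = x[3 * i + 1] - x[3 * j + 1];
        double dz = x[3 * i + 2] - x[3 * j + 2];
        if (dx * dx + dy * dy + dz * dz <= rl2) {
          pairs.push_back(i);
          pairs.push_back(j);
        }
      }
    ref.assign(x, x + 3 * N);
  }

  bool stale(const double *x, int N) const {
    double lim = 0.25 * skin * skin;  // any bead moved >= skin/2
    for (int i = 0; i < 3 * N; i += 3) {
      double dx = x[i] - ref[i], dy = x[i + 1] - ref[i + 1],
             dz = x[i + 2] - ref[i + 2];
      if (dx * dx + dy * dy + dz * dz >= lim) return true;
    }
    return false;
  }
};

// ---------------------------------------------------------------- forces

struct EnergyTerms {
  double wca = 0, fene = 0, bend = 0, smc_spring = 0, smc_angular = 0,
         field = 0;
  double total() const {
    return wca + fene + bend + smc_spring + smc_angular + field;
  }
};

static inline void wca_pair(const double *xi, const double *xj, double eps,
                            double sig, double rc2, double *F, int i, int j,
                            double &energy, bool want_energy) {
  double d[3] = {xi[0] - xj[0], xi[1] - xj[1], xi[2] - xj[2]};
  double r2 = dot3(d, d);
  if (r2 >= rc2 || r2 <= 0) return;
  double sr2 = sig * sig / r2, sr6 = sr2 * sr2 * sr2;
  double coef = 24.0 * eps * (2.0 * sr6 * sr6 - sr6) / r2;
  if (F) {
    for (int k = 0; k < 3; ++k) {
      F[3 * i + k] += coef * d[k];
      F[3 * j + k] -= coef * d[k];
    }
  }
  if (want_energy) energy += 4.0 * eps * (sr6 * sr6 - sr6) + eps;
}

// Computes forces (if F non-null) and energy terms (if terms non-null).
// Throws on FENE overstretch.
static void compute_forces(std::vector<double> &x, int N, const FFParams &p,
                           const Field &f, const SMC &smc,
                           const NeighborList *nl, double *F,
                           EnergyTerms *terms, bool clamp_angular = false) {
  if (F) std::fill(F, F + 3 * N, 0.0);
  bool we = terms != nullptr;

  // non-bonded WCA
  if (p.wca_on) {
    if (nl) {
      double dummy = 0;
      const std::vector<int> &pr = nl->pairs;
      for (size_t k = 0; k < pr.size(); k += 2)
        wca_pair(&x[3 * pr[k]], &x[3 * pr[k + 1]], p.eps, p.sigma, p.rc2, F,
                 pr[k], pr[k + 1], we ? terms->wca : dummy, we);
    } else {
      double dummy = 0;
      for (int i = 0; i < N; ++i)
        for (int j = i + 2; j < N; ++j)
          wca_pair(&x[3 * i], &x[3 * j], p.eps, p.sigma, p.rc2, F, i, j,
                   we ? terms->wca : dummy, we);
    }
  }

  // FENE backbone (includes its own WCA part)
  if (p.bonds_on) {
    double R02 = p.fene_R0 * p.fene_R0;
    for (int i = 0; i + 1 < N; ++i) {
      int j = i + 1;
      double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                     x[3 * i + 2] - x[3 * j + 2]};
      double r2 = dot3(d, d);
      if (r2 >= R02)
        throw std::runtime_error(
            "FENE bond overstretched (bond length >= R0); the integration "
            "timestep is likely too large for the current forces");
      double denom = 1.0 - r2 / R02;
      double coef = -p.fene_k / denom;  // force prefactor on separation vector
      if (F)
        for (int k = 0; k < 3; ++k) {
          F[3 * i + k] += coef * d[k];
          F[3 * j + k] -= coef * d[k];
        }
      double dummy = 0;
      wca_pair(&x[3 * i], &x[3 * j], p.eps, p.sigma, p.rc2, F, i, j, dummy,
               false);
      if (we) {
        terms->fene += -0.5 * p.fene_k * R02 * std::log(denom);
        double r2w = r2;
        if (r2w < p.rc2) {
          double sr2 = p.sigma * p.sigma / r2w, sr6 = sr2 * sr2 * sr2;
          terms->fene += 4.0 * p.eps * (sr6 * sr6 - sr6) + p.eps;
        }
      }
    }
  }

  // Kratky-Porod bending on consecutive triplets
  if (p.bend_on && p.kp > 0 && N >= 3) {
    for (int i = 1; i + 1 < N; ++i) {
      double b1[3], b2[3];
      for (int k = 0; k < 3; ++k) {
        b1[k] = x[3 * i + k] - x[3 * (i - 1) + k];
        b2[k] = x[3 * (i + 1) + k] - x[3 * i + k];
      }
      double n1 = norm3(b1), n2 = norm3(b2);
      if (n1 < 1e-12 || n2 < 1e-12) continue;
      double inv = 1.0 / (n1 * n2);
      double c = dot3(b1, b2) * inv;
      if (c > 1.0) c = 1.0;
      if (c < -1.0) c = -1.0;
      if (we) terms->bend += p.kp * (1.0 - c);
      if (F) {
        // F = -grad E = kp * grad cos(theta)
        double g1[3], g2[3];
        for (int k = 0; k < 3; ++k) {
          g1[k] = b2[k] * inv - c * b1[k] / (n1 * n1);
          g2[k] = b1[k] * inv - c * b2[k] / (n2 * n2);
        }
        for (int k = 0; k < 3; ++k) {
          F[3 * (i - 1) + k] += -p.kp * g1[k];
          F[3 * i + k] += p.kp * (g1[k] - g2[k]);
          F[3 * (i + 1) + k] += p.kp * g2[k];
        }
      }
    }
  }

  // SMC harmonic springs
  if (smc.loaded) {
    int spr[4];
    int nspr = 0;
    spr[nspr++] = smc.a;
    spr[nspr++] = smc.h;
    if (smc.two_springs()) {
      spr[nspr++] = smc.a_in();
      spr[nspr++] = smc.h_in();
    }
    for (int b = 0; b + 1 < nspr; b += 2) {
      int i = spr[b], j = spr[b + 1];
      double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                     x[3 * i + 2] - x[3 * j + 2]};
      double r = norm3(d);
      if (r < 1e-12) continue;
      if (we) terms->smc_spring += p.smc_k * (r - p.smc_r0) * (r - p.smc_r0);
      if (F) {
        double coef = -2.0 * p.smc_k * (r - p.smc_r0) / r;
        for (int k = 0; k < 3; ++k) {
          F[3 * i + k] += coef * d[k];
          F[3 * j + k] -= coef * d[k];
        }
      }
    }
    // torsion-variant angular bundle: central-difference forces
    if (smc.angular()) {
      if (we) terms->smc_angular += smc_angular_energy(x.data(), N, smc, p);
      if (F) {
        int beads[6];
        int nb = 0;
        beads[nb++] = smc.a;
        beads[nb++] = smc.h;
        beads[nb++] = smc.a_in();
        beads[nb++] = smc.h_in();
        if (smc.variant == 4) {
          if (smc.a_out() >= 0 && smc.a_out() < N) beads[nb++] = smc.a_out();
          if (smc.h_out() >= 0 && smc.h_out() < N) beads[nb++] = smc.h_out();
        }
        for (int b = 0; b < nb; ++b)
          for (int k = 0; k < 3; ++k) {
            double &c = x[3 * beads[b] + k];
            double save = c;
            c = save + H_FD;
            double ep = smc_angular_energy(x.data(), N, smc, p);
            c = save - H_FD;
            double em = smc_angular_energy(x.data(), N, smc, p);
            c = save;
            double g = (ep - em) / (2.0 * H_FD);
            // the dihedral gradient diverges as a segment's in-plane
            // projection vanishes; inside the integrator, cap it so this
            // bounded-energy term cannot destabilise the timestep (the
            // cap only engages in rare near-degenerate frames)
            if (clamp_angular) {
              if (g > 100.0) g = 100.0;
              if (g < -100.0) g = -100.0;
            }
            F[3 * beads[b] + k] -= g;
          }
      }
    }
  }

  // external field: slab walls (harmonic beyond the margin) and end tether
  if (f.slab) {
    double bound = 0.5 * f.slab_gap - f.wall_margin;
    if (bound < 0) bound = 0;
    for (int i = 0; i < N; ++i) {
      double z = x[3 * i + 2];
      double ex = 0;
      if (z > bound)
        ex = z - bound;
      else if (z < -bound)
        ex = z + bound;
      if (ex != 0) {
        if (F) F[3 * i + 2] -= f.wall_k * ex;
        if (we) terms->field += 0.5 * f.wall_k * ex * ex;
      }
    }
  }
  if (f.tether && N >= 2 && f.tether_f > 0) {
    // constant force pulling the two end beads apart along x
    if (F) {
      F[0] -= f.tether_f;
      F[3 * (N - 1)] += f.tether_f;
    }
    if (we) terms->field += -f.tether_f * (x[3 * (N - 1)] - x[0]);
  }
}

// ---------------------------------------------------------------- capture

struct CaptureGeom {
  double apex[3], u[3];
  bool ok = false;
};

static CaptureGeom capture_geom(const double *x, const SMC &smc) {
  CaptureGeom g;
  const double *ra = x + 3 * smc.a;
  const double *rh = x + 3 * smc.h;
  double dir[3] = {rh[0] - ra[0], rh[1] - ra[1], rh[2] - ra[2]};
  double nd = norm3(dir);
  if (nd < 1e-9) return g;
  for (int k = 0; k < 3; ++k) g.u[k] = dir[k] / nd;
  if (smc.variant == 2) {  // apex at barycentre of the four bonded beads
    int ai = smc.a_in(), hi = smc.h_in();
    for (int k = 0; k < 3; ++k)
      g.apex[k] =
          0.25 * (ra[k] + rh[k] + x[3 * ai + k] + x[3 * hi + k]);
  } else {
    for (int k = 0; k < 3; ++k) g.apex[k] = rh[k];
  }
  g.ok = true;
  return g;
}

static std::vector<int> find_candidates_core(const double *x, int N,
                                             const SMC &smc) {
  std::vector<int> out;
  CaptureGeom g = capture_geom(x, smc);
  if (!g.ok) return out;
  double cosg = std::cos(0.5 * smc.gamma_deg * M_PI / 180.0);
  double rmin2 = smc.rmin * smc.rmin, rmax2 = smc.rmax * smc.rmax;
  int hi = smc.h_in();
  for (int j = 1; j <= N - 2; ++j) {  // keep one bead clear of each terminus
    if (j == smc.h || j == hi) continue;             // current head pair
    if (std::abs(j - smc.h) > smc.jump_cap) continue;  // 1D jump cap
    if (std::abs(j - smc.a) < 3) continue;             // bond bookkeeping
    double pos[3] = {x[3 * j] - g.apex[0], x[3 * j + 1] - g.apex[1],
                     x[3 * j + 2] - g.apex[2]};
    double d2 = dot3(pos, pos);
    if (d2 < rmin2 || d2 > rmax2) continue;
    double cosang = dot3(g.u, pos) / std::sqrt(d2);
    bool in_cone = smc.cone_ge ? (cosang >= cosg) : (cosang <= cosg);
    if (in_cone) out.push_back(j);
  }
  return out;
}

// ---------------------------------------------------------------- dynamics

// integrator = 0: BAOAB Langevin (inertial, m = 1); 1: overdamped
// Euler-Maruyama (the strict Brownian update; needs a much smaller dt).
struct Integrator {
  double dt = 0.01, temperature = 1.0, friction = 1.0;
  int scheme = 0;
  double mob, noise, c1, c2;
  void derive() {
    mob = dt / friction;
    noise = std::sqrt(2.0 * temperature * dt / friction);
    c1 = std::exp(-friction * dt);  // m = 1
    c2 = std::sqrt(temperature * (1.0 - c1 * c1));
  }
};

// Maxwell-Boltzmann velocities (m = 1)
static void thermalize(std::vector<double> &v, double temperature,
                       Xoshiro &rng, const Ziggurat &zig) {
  double s = std::sqrt(temperature);
  for (size_t i = 0; i < v.size(); ++i) v[i] = s * zig.draw(rng);
}

static void run_bd(std::vector<double> &x, std::vector<double> &v, int N,
                   const FFParams &p, const Field &f, const SMC &smc,
                   Integrator &ic, long nsteps, Xoshiro &rng,
                   const Ziggurat &zig, NeighborList &nl,
                   std::vector<double> &F) {
  ic.derive();
  bool use_nl = p.wca_on && N > 16;
  if (use_nl) nl.build(x.data(), N, std::sqrt(p.rc2));
  if (ic.scheme == 1) {  // overdamped Euler-Maruyama
    for (long s = 0; s < nsteps; ++s) {
      if (use_nl && nl.stale(x.data(), N))
        nl.build(x.data(), N, std::sqrt(p.rc2));
      compute_forces(x, N, p, f, smc, use_nl ? &nl : nullptr, F.data(),
                     nullptr, true);
      for (int i = 0; i < 3 * N; ++i)
        x[i] += ic.mob * F[i] + ic.noise * zig.draw(rng);
    }
    return;
  }
  // BAOAB: B (half kick) A (half drift) O (friction+noise) A B
  double h2 = 0.5 * ic.dt;
  compute_forces(x, N, p, f, smc, use_nl ? &nl : nullptr, F.data(), nullptr,
                 true);
  for (long s = 0; s < nsteps; ++s) {
    for (int i = 0; i < 3 * N; ++i) {
      v[i] += h2 * F[i];
      x[i] += h2 * v[i];
    }
    for (int i = 0; i < 3 * N; ++i)
      v[i] = ic.c1 * v[i] + ic.c2 * zig.draw(rng);
    for (int i = 0; i < 3 * N; ++i) x[i] += h2 * v[i];
    if (use_nl && nl.stale(x.data(), N))
      nl.build(x.data(), N, std::sqrt(p.rc2));
    compute_forces(x, N, p, f, smc, use_nl ? &nl : nullptr, F.data(),
                   nullptr, true);
    for (int i = 0; i < 3 * N; ++i) v[i] += h2 * F[i];
  }
}

// ---------------------------------------------------------------- exports

// [[Rcpp::export]]
NumericVector cpp_energy_terms(NumericMatrix pos, List params,
                               Nullable<List> smc = R_NilValue,
                               Nullable<List> field = R_NilValue) {
  int N = pos.nrow();
  std::vector<double> x(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);
  FFParams p = params_from_list(params);
  Field f = field_from_list(field);
  SMC s = smc_from_list(smc);
  EnergyTerms t;
  compute_forces(x, N, p, f, s, nullptr, nullptr, &t);
  return NumericVector::create(
      _["wca"] = t.wca, _["fene"] = t.fene, _["bend"] = t.bend,
      _["smc_spring"] = t.smc_spring, _["smc_angular"] = t.smc_angular,
      _["field"] = t.field, _["total"] = t.total());
}

// [[Rcpp::export]]
NumericMatrix cpp_total_forces(NumericMatrix pos, List params,
                               Nullable<List> smc = R_NilValue,
                               Nullable<List> field = R_NilValue) {
  int N = pos.nrow();
  std::vector<double> x(3 * N), F(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);
  FFParams p = params_from_list(params);
  Field f = field_from_list(field);
  SMC s = smc_from_list(smc);
  compute_forces(x, N, p, f, s, nullptr, F.data(), nullptr);
  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = F[3 * i + k];
  return out;
}

// Steepest descent with backtracking; energy is guaranteed non-increasing.
// [[Rcpp::export]]
List cpp_minimize(NumericMatrix pos, List params,
                  Nullable<List> smc = R_NilValue,
                  Nullable<List> field = R_NilValue, int max_steps = 200,
                  double max_disp = 0.05, double ftol = 1e-8) {
  int N = pos.nrow();
  std::vector<double> x(3 * N), F(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);
  FFParams p = params_from_list(params);
  Field f = field_from_list(field);
  SMC s = smc_from_list(smc);
  EnergyTerms t;
  compute_forces(x, N, p, f, s, nullptr, F.data(), &t);
  double e = t.total();
  std::vector<double> energies;
  energies.push_back(e);
  for (int it = 0; it < max_steps; ++it) {
    double fmax = 0;
    for (int i = 0; i < 3 * N; ++i) fmax = std::max(fmax, std::fabs(F[i]));
    if (fmax < ftol) break;
    double alpha = max_disp / fmax;
    std::vector<double> xt(3 * N);
    double et = e;
    bool accepted = false;
    for (int bt = 0; bt < 12; ++bt) {
      for (int i = 0; i < 3 * N; ++i) xt[i] = x[i] + alpha * F[i];
      EnergyTerms tt;
      bool bad = false;
      try {
        compute_forces(xt, N, p, f, s, nullptr, nullptr, &tt);
      } catch (...) {
        bad = true;
      }
      if (!bad && tt.total() <= e) {
        et = tt.total();
        accepted = true;
        break;
      }
      alpha *= 0.5;
    }
    if (!accepted) break;
    x = xt;
    e = et;
    energies.push_back(e);
    compute_forces(x, N, p, f, s, nullptr, F.data(), nullptr);
  }
  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = x[3 * i + k];
  return List::create(_["positions"] = out, _["energy"] = e,
                      _["energies"] = wrap(energies));
}

// Plain Brownian dynamics (no capture attempts); optional conformation
// sampling every `sample_every` steps.
// [[Rcpp::export]]
List cpp_run_dynamics(NumericMatrix pos, List params, long nsteps, double dt,
                      Nullable<List> smc = R_NilValue,
                      Nullable<List> field = R_NilValue,
                      double temperature = 1.0, double friction = 1.0,
                      int seed = 1, int replicate = 1, int stream = 0,
                      long sample_every = 0, int scheme = 0) {
  int N = pos.nrow();
  std::vector<double> x(3 * N), v(3 * N, 0.0), F(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);
  FFParams p = params_from_list(params);
  Field f = field_from_list(field);
  SMC s = smc_from_list(smc);
  Integrator ic;
  ic.dt = dt;
  ic.temperature = temperature;
  ic.friction = friction;
  ic.scheme = scheme;
  Xoshiro rng;
  rng.seed((uint64_t)seed, (uint64_t)replicate, (uint64_t)stream);
  static const Ziggurat zig;
  if (scheme == 0) thermalize(v, temperature, rng, zig);
  NeighborList nl;
  List samples;
  std::vector<double> sample_times;
  if (sample_every > 0) {
    long done = 0;
    while (done < nsteps) {
      long chunk = std::min(sample_every, nsteps - done);
      run_bd(x, v, N, p, f, s, ic, chunk, rng, zig, nl, F);
      done += chunk;
      NumericMatrix snap(N, 3);
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < 3; ++k) snap(i, k) = x[3 * i + k];
      samples.push_back(snap);
      sample_times.push_back(done * dt);
    }
  } else {
    run_bd(x, v, N, p, f, s, ic, nsteps, rng, zig, nl, F);
  }
  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = x[3 * i + k];
  return List::create(_["positions"] = out, _["samples"] = samples,
                      _["sample_times"] = wrap(sample_times));
}

// [[Rcpp::export]]
IntegerVector cpp_find_candidates(NumericMatrix pos, List smc) {
  int N = pos.nrow();
  std::vector<double> x(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);
  SMC s = smc_from_list(List(smc));
  std::vector<int> cand = find_candidates_core(x.data(), N, s);
  IntegerVector out(cand.size());
  for (size_t i = 0; i < cand.size(); ++i) out[i] = cand[i] + 1;
  return out;
}

// One capture attempt on a frozen conformation (unit-test surface; the same
// code path as the extrusion loop).
// [[Rcpp::export]]
List cpp_attempt_step(NumericMatrix pos, List smc, int seed = 1,
                      int replicate = 1) {
  int N = pos.nrow();
  std::vector<double> x(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);
  SMC s = smc_from_list(List(smc));
  std::vector<int> cand = find_candidates_core(x.data(), N, s);
  bool success = !cand.empty();
  int old_head = s.h, new_head = s.h;
  if (success) {
    Xoshiro rng;
    rng.seed((uint64_t)seed, (uint64_t)replicate, 2);
    new_head = cand[rng.randint((int)cand.size())];
    if (std::abs(new_head - s.a) < 3)
      throw std::runtime_error("internal error: new head within 3 beads of anchor");
  }
  return List::create(_["success"] = success, _["old_head"] = old_head + 1,
                      _["new_head"] = new_head + 1,
                      _["signed_step"] = old_head - new_head,
                      _["candidate_count"] = (int)cand.size());
}

// Full extrusion run: alternate Delta_t of Brownian dynamics with one capture
// attempt, starting from a loaded conformation. Returns the per-attempt event
// log, the oriented-loop-length trace and the final conformation.
// [[Rcpp::export]]
List cpp_extrude(NumericMatrix pos, List params, List smc, double run_time,
                 double dt, double attempt_interval,
                 Nullable<List> field = R_NilValue, double temperature = 1.0,
                 double friction = 1.0, int seed = 1, int replicate = 1,
                 int scheme = 0) {
  int N = pos.nrow();
  std::vector<double> x(3 * N), v(3 * N, 0.0), F(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);
  FFParams p = params_from_list(params);
  Field f = field_from_list(field);
  SMC s = smc_from_list(List(smc));
  Integrator ic;
  ic.dt = dt;
  ic.temperature = temperature;
  ic.friction = friction;
  ic.scheme = scheme;
  Xoshiro rng_thermal, rng_capture;
  rng_thermal.seed((uint64_t)seed, (uint64_t)replicate, 0);
  rng_capture.seed((uint64_t)seed, (uint64_t)replicate, 2);
  static const Ziggurat zig;
  if (scheme == 0) thermalize(v, temperature, rng_thermal, zig);
  NeighborList nl;

  long steps_per = (long)std::lround(attempt_interval / dt);
  int n_attempts = (int)std::floor(run_time / attempt_interval + 1e-9);

  std::vector<double> ev_time(n_attempts), tr_time(n_attempts + 1);
  std::vector<int> ev_success(n_attempts), ev_old(n_attempts),
      ev_new(n_attempts), ev_step(n_attempts), ev_ncand(n_attempts),
      tr_l(n_attempts + 1);
  tr_time[0] = 0.0;
  tr_l[0] = s.a - s.h;

  for (int at = 0; at < n_attempts; ++at) {
    run_bd(x, v, N, p, f, s, ic, steps_per, rng_thermal, zig, nl, F);
    std::vector<int> cand = find_candidates_core(x.data(), N, s);
    int old_head = s.h;
    bool success = !cand.empty();
    if (success) {
      int nh = cand[rng_capture.randint((int)cand.size())];
      s.h = nh;  // anchor never changes; bonds follow the SMC state
    }
    ev_time[at] = (at + 1) * attempt_interval;
    ev_success[at] = success ? 1 : 0;
    ev_old[at] = old_head + 1;
    ev_new[at] = s.h + 1;
    ev_step[at] = old_head - s.h;  // Delta l with l = n_a - n_h
    ev_ncand[at] = (int)cand.size();
    tr_time[at + 1] = (at + 1) * attempt_interval;
    tr_l[at + 1] = s.a - s.h;
  }

  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = x[3 * i + k];
  return List::create(
      _["time"] = wrap(ev_time), _["success"] = wrap(ev_success),
      _["old_head"] = wrap(ev_old), _["new_head"] = wrap(ev_new),
      _["signed_step"] = wrap(ev_step), _["candidate_count"] = wrap(ev_ncand),
      _["trace_time"] = wrap(tr_time), _["trace_l"] = wrap(tr_l),
      _["final_head"] = s.h + 1, _["positions"] = out);
}

// Standard-normal draws from the kernel's sampler (moment sanity checks).
// [[Rcpp::export]]
NumericVector cpp_gauss(int n, int seed = 1) {
  Xoshiro rng;
  rng.seed((uint64_t)seed, 1, 0);
  static const Ziggurat zig;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = zig.draw(rng);
  return out;
}
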