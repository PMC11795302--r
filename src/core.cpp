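// Bonded-force kernels and the overdamped Euler-Maruyama integrator for the
// translate/relax compression protocol. Positions in nm, forces in pN,
// energies in pN nm, times in s. Self-contained counter-style RNG
// (splitmix64-seeded xoshiro256++ with a ziggurat normal sampler) so that a
// given seed reproduces a trajectory bitwise, independent of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ------

namespace fcrng {

struct Xoshiro256pp {
  uint64_t s[4];

  explicit Xoshiro256pp(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// Marsaglia-Tsang 128-layer ziggurat for standard normals.
struct Ziggurat {
  uint32_t kn[128];
  double wn[128], fn[128];

  Ziggurat() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }

  inline double draw(Xoshiro256pp& rng) const {
    const double r = 3.442619855899;
    for (;;) {
      int32_t hz = (int32_t)(uint32_t)(rng.next() >> 32);
      uint32_t iz = (uint32_t)hz & 127u;
      if ((uint32_t)std::abs(hz) < kn[iz]) return hz * wn[iz];
      if (iz == 0) {  // tail
        double x, y;
        do {
          x = -std::log(rng.unif()) / r;
          y = -std::log(rng.unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -(r + x);
      }
      double x = hz * wn[iz];
      if (fn[iz] + rng.unif() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

static const Ziggurat zigg;

}  // namespace fcrng

// ------------------------------------------------------------- forces ------

struct Terms {
  std::vector<int> bi, bj;          // bonds
  std::vector<double> bk, br0;
  std::vector<int> ai;              // angles: beads ai, ai+1, ai+2
  std::vector<double> ak, at0;
  std::vector<int> di;              // dihedrals: beads di .. di+3
  std::vector<double> dk, dp0;
  std::vector<double> dsin0, dcos0; // precomputed sin/cos of dihedral targets
};

static Terms unpack_terms(const List& terms) {
  Terms t;
  t.bi = as<std::vector<int> >(terms["bonds_i"]);
  t.bj = as<std::vector<int> >(terms["bonds_j"]);
  t.bk = as<std::vector<double> >(terms["bonds_k"]);
  t.br0 = as<std::vector<double> >(terms["bonds_r0"]);
  t.ai = as<std::vector<int> >(terms["ang_i"]);
  t.ak = as<std::vector<double> >(terms["ang_k"]);
  t.at0 = as<std::vector<double> >(terms["ang_t0"]);
  t.di = as<std::vector<int> >(terms["dih_i"]);
  t.dk = as<std::vector<double> >(terms["dih_k"]);
  t.dp0 = as<std::vector<double> >(terms["dih_p0"]);
  t.dsin0.resize(t.dp0.size());
  t.dcos0.resize(t.dp0.size());
  for (size_t i = 0; i < t.dp0.size(); ++i) {
    t.dsin0[i] = std::sin(t.dp0[i]);
    t.dcos0[i] = std::cos(t.dp0[i]);
  }
  return t;
}

// Accumulate bonded forces into f (length 3n, xyz interleaved); returns energy.
static double bonded_forces(const double* p, int n, const Terms& t,
                            double* f) {
  double energy = 0.0;
  (void)n;
  // harmonic bonds: U = 1/2 k (r - r0)^2
  for (size_t m = 0; m < t.bi.size(); ++m) {
    const double* pi = p + 3 * t.bi[m];
    const double* pj = p + 3 * t.bj[m];
    double dx = pj[0] - pi[0], dy = pj[1] - pi[1], dz = pj[2] - pi[2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - t.br0[m];
    energy += 0.5 * t.bk[m] * dr * dr;
    double fac = -t.bk[m] * dr / r;  // force on j along +d
    double* fi = f + 3 * t.bi[m];
    double* fj = f + 3 * t.bj[m];
    fj[0] += fac * dx; fj[1] += fac * dy; fj[2] += fac * dz;
    fi[0] -= fac * dx; fi[1] -= fac * dy; fi[2] -= fac * dz;
  }
  // harmonic angles: U = 1/2 k (theta - theta0)^2, vertex at i+1
  for (size_t m = 0; m < t.ai.size(); ++m) {
    int i = t.ai[m];
    const double* pa = p + 3 * i;
    const double* pb = p + 3 * (i + 1);
    const double* pc = p + 3 * (i + 2);
    double ux = pa[0] - pb[0], uy = pa[1] - pb[1], uz = pa[2] - pb[2];
    double vx = pc[0] - pb[0], vy = pc[1] - pb[1], vz = pc[2] - pb[2];
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    double c = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
    double th = std::acos(c);
    double dth = th - t.at0[m];
    energy += 0.5 * t.ak[m] * dth * dth;
    double s = std::sqrt(1.0 - c * c);
    if (s < 1e-8) s = 1e-8;
    double coef = t.ak[m] * dth / s;  // = -dU/dtheta * dtheta/dcos
    // dcos/dra = (v_hat - c u_hat)/nu ; dcos/drc = (u_hat - c v_hat)/nv
    double fax = coef * (vx / nv - c * ux / nu) / nu;
    double fay = coef * (vy / nv - c * uy / nu) / nu;
    double faz = coef * (vz / nv - c * uz / nu) / nu;
    double fcx = coef * (ux / nu - c * vx / nv) / nv;
    double fcy = coef * (uy / nu - c * vy / nv) / nv;
    double fcz = coef * (uz / nu - c * vz / nv) / nv;
    double* fa = f + 3 * i;
    double* fb = f + 3 * (i + 1);
    double* fc = f + 3 * (i + 2);
    fa[0] += fax; fa[1] += fay; fa[2] += faz;
    fc[0] += fcx; fc[1] += fcy; fc[2] += fcz;
    fb[0] -= fax + fcx; fb[1] -= fay + fcy; fb[2] -= faz + fcz;
  }
  // cosine dihedrals: U = k (1 + cos(phi - phi0 - pi)) = k (1 - cos(phi - phi0))
  for (size_t m = 0; m < t.di.size(); ++m) {
    int i = t.di[m];
    const double* p1 = p + 3 * i;
    const double* p2 = p + 3 * (i + 1);
    const double* p3 = p + 3 * (i + 2);
    const double* p4 = p + 3 * (i + 3);
    double b1x = p2[0] - p1[0], b1y = p2[1] - p1[1], b1z = p2[2] - p1[2];
    double b2x = p3[0] - p2[0], b2y = p3[1] - p2[1], b2z = p3[2] - p2[2];
    double b3x = p4[0] - p3[0], b3y = p4[1] - p3[1], b3z = p4[2] - p3[2];
    // m = b1 x b2, nvec = b2 x b3
    double mx = b1y * b2z - b1z * b2y;
    double my = b1z * b2x - b1x * b2z;
    double mz = b1x * b2y - b1y * b2x;
    double nx = b2y * b3z - b2z * b3y;
    double ny = b2z * b3x - b2x * b3z;
    double nz = b2x * b3y - b2y * b3x;
    double m2 = mx * mx + my * my + mz * mz;
    double n2 = nx * nx + ny * ny + nz * nz;
    double nb2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
    if (m2 < 1e-20 || n2 < 1e-20) continue;  // collinear: torsion undefined
    // phi = atan2((m x b2_hat) . n, m . n)  (IUPAC torsion convention);
    // sin/cos of (phi - phi0) are formed directly from the unnormalised
    // sine/cosine parts, avoiding atan2/sin/cos in the inner loop
    double cxx = my * nz - mz * ny;
    double cxy = mz * nx - mx * nz;
    double cxz = mx * ny - my * nx;
    double sraw = -(cxx * b2x + cxy * b2y + cxz * b2z) / nb2;
    double craw = mx * nx + my * ny + mz * nz;
    double inv = 1.0 / std::sqrt(sraw * sraw + craw * craw);
    double sphi = sraw * inv, cphi = craw * inv;
    double cdphi = cphi * t.dcos0[m] + sphi * t.dsin0[m];
    double sdphi = sphi * t.dcos0[m] - cphi * t.dsin0[m];
    energy += t.dk[m] * (1.0 - cdphi);
    double dUdphi = t.dk[m] * sdphi;
    // gradient of phi (verified against central differences):
    // dphi/dr1 = (|b2|/|m|^2) m, dphi/dr4 = -(|b2|/|n|^2) n,
    // dphi/dr2 = -(1+s12) dphi/dr1 + s32 dphi/dr4,
    // dphi/dr3 = s12 dphi/dr1 - (1+s32) dphi/dr4
    double gax = nb2 / m2 * mx, gay = nb2 / m2 * my, gaz = nb2 / m2 * mz;
    double gdx = -nb2 / n2 * nx, gdy = -nb2 / n2 * ny, gdz = -nb2 / n2 * nz;
    double s12 = (b1x * b2x + b1y * b2y + b1z * b2z) / (nb2 * nb2);
    double s32 = (b3x * b2x + b3y * b2y + b3z * b2z) / (nb2 * nb2);
    double gbx = -(1 + s12) * gax + s32 * gdx;
    double gby = -(1 + s12) * gay + s32 * gdy;
    double gbz = -(1 + s12) * gaz + s32 * gdz;
    double gcx = s12 * gax - (1 + s32) * gdx;
    double gcy = s12 * gay - (1 + s32) * gdy;
    double gcz = s12 * gaz - (1 + s32) * gdz;
    double* f1 = f + 3 * i;
    double* f2 = f + 3 * (i + 1);
    double* f3 = f + 3 * (i + 2);
    double* f4 = f + 3 * (i + 3);
    f1[0] -= dUdphi * gax; f1[1] -= dUdphi * gay; f1[2] -= dUdphi * gaz;
    f2[0] -= dUdphi * gbx; f2[1] -= dUdphi * gby; f2[2] -= dUdphi * gbz;
    f3[0] -= dUdphi * gcx; f3[1] -= dUdphi * gcy; f3[2] -= dUdphi * gcz;
    f4[0] -= dUdphi * gdx; f4[1] -= dUdphi * gdy; f4[2] -= dUdphi * gdz;
  }
  return energy;
}

// [[Rcpp::export]]
List forces_cpp(NumericMatrix pts, List terms) {
  int n = pts.nrow();
  Terms t = unpack_terms(terms);
  std::vector<double> p(3 * n), f(3 * n, 0.0);
  for (int i = 0; i < n; ++i) {
    p[3 * i] = pts(i, 0);
    p[3 * i + 1] = pts(i, 1);
    p[3 * i + 2] = pts(i, 2);
  }
  double e = bonded_forces(p.data(), n, t, f.data());
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = f[3 * i];
    out(i, 1) = f[3 * i + 1];
    out(i, 2) = f[3 * i + 2];
  }
  return List::create(_["forces"] = out, _["energy"] = e);
}

// --------------------------------------------------------- integrator ------

// Runs the translate/relax protocol. Cycle = translate_steps + relax_steps
// protocol steps, each integrated with n_sub Euler-Maruyama substeps of
// dt_protocol / n_sub. Anchored particles never integrate; the subset listed
// in `moved` is displaced along -x by delta_cycle per cycle, spread linearly
// over the translate substeps. Frames are recorded after the cycles listed in
// save_cycles (0 = initial state). Stops early once the x-projected extent
// x[last] - x[first] reaches target_x_extent (ignored if negative).
// [[Rcpp::export]]
List simulate_cpp(NumericMatrix init, List terms,
                  IntegerVector anchored, IntegerVector moved,
                  double delta_cycle, int translate_steps, int relax_steps,
                  int n_sub, double dt_protocol, double kT, double gamma,
                  double seed, NumericVector save_cycles,
                  double max_cycles, double target_x_extent) {
  const int n = init.nrow();
  Terms t = unpack_terms(terms);
  std::vector<double> p(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i) {
    p[3 * i] = init(i, 0);
    p[3 * i + 1] = init(i, 1);
    p[3 * i + 2] = init(i, 2);
  }
  std::vector<char> is_free(n, 1);
  for (int k = 0; k < anchored.size(); ++k) is_free[anchored[k]] = 0;
  std::vector<int> mv = as<std::vector<int> >(moved);

  fcrng::Xoshiro256pp rng((uint64_t)seed);
  const double dt = dt_protocol / n_sub;
  const double mob = dt / gamma;
  const double sig = std::sqrt(2.0 * kT * dt / gamma);
  const double dx_sub =
      delta_cycle / (double)(translate_steps * n_sub);

  const int n_save = save_cycles.size();
  NumericMatrix frames(n_save, 3 * n);
  NumericVector frame_cycles(n_save);
  int save_ptr = 0;
  auto record = [&](double cycle) {
    if (save_ptr < n_save) {
      for (int i = 0; i < 3 * n; ++i) frames(save_ptr, i) = p[i];
      frame_cycles[save_ptr] = cycle;
      ++save_ptr;
    }
  };
  if (n_save > 0 && save_cycles[0] == 0) record(0.0);

  const int cycle_steps = translate_steps + relax_steps;
  double cycles_run = 0;
  bool reached = false;
  for (double cyc = 1; cyc <= max_cycles; cyc += 1) {
    for (int step = 0; step < cycle_steps; ++step) {
      bool translating = step < translate_steps;
      for (int sub = 0; sub < n_sub; ++sub) {
        std::fill(f.begin(), f.end(), 0.0);
        bonded_forces(p.data(), n, t, f.data());
        if (kT > 0) {
          for (int i = 0; i < n; ++i) {
            if (!is_free[i]) continue;
            p[3 * i] += mob * f[3 * i] + sig * fcrng::zigg.draw(rng);
            p[3 * i + 1] += mob * f[3 * i + 1] + sig * fcrng::zigg.draw(rng);
            p[3 * i + 2] += mob * f[3 * i + 2] + sig * fcrng::zigg.draw(rng);
          }
        } else {
          for (int i = 0; i < n; ++i) {
            if (!is_free[i]) continue;
            p[3 * i] += mob * f[3 * i];
            p[3 * i + 1] += mob * f[3 * i + 1];
            p[3 * i + 2] += mob * f[3 * i + 2];
          }
        }
        if (translating && dx_sub != 0.0) {
          for (size_t k = 0; k < mv.size(); ++k) p[3 * mv[k]] -= dx_sub;
        }
      }
    }
    cycles_run = cyc;
    // blow-up guard
    for (int i = 0; i < 3 * n; ++i) {
      if (!std::isfinite(p[i]))
        stop("numerical blow-up at cycle %g (coordinate %d non-finite); "
             "reduce the timestep", cyc, i + 1);
    }
    bool due = save_ptr < n_save && save_cycles[save_ptr] <= cyc;
    if (target_x_extent >= 0 &&
        (p[3 * (n - 1)] - p[0]) <= target_x_extent) {
      record(cyc);
      reached = true;
      break;
    }
    if (due) record(cyc);
    if (((long long)cyc) % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  // fill any unsaved slots with the final state
  while (save_ptr < n_save) record(cycles_run);

  return List::create(_["frames"] = frames,
                      _["frame_cycles"] = frame_cycles,
                      _["cycles_run"] = cycles_run,
                      _["reached_target"] = reached);
}

// Single Euler-Maruyama step exposed for tests and for the R-level
// step_overdamped wrapper (noise drawn here with the package RNG).
// [[Rcpp::export]]
NumericMatrix step_cpp(NumericMatrix pts, NumericMatrix forces,
                       double kT, double gamma, double dt,
                       IntegerVector fixed, double seed) {
  int n = pts.nrow();
  fcrng::Xoshiro256pp rng((uint64_t)seed);
  std::vector<char> is_free(n, 1);
  for (int k = 0; k < fixed.size(); ++k) is_free[fixed[k]] = 0;
  const double mob = dt / gamma;
  const double sig = kT > 0 ? std::sqrt(2.0 * kT * dt / gamma) : 0.0;
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < 3; ++d) {
      double xi = (sig > 0 && is_free[i]) ? fcrng::zigg.draw(rng) : 0.0;
      out(i, d) = pts(i, d) +
        (is_free[i] ? mob * forces(i, d) + sig * xi : 0.0);
    }
  }
  return out;
}

// Standard-normal draws from the package RNG (for RNG sanity tests).
// [[Rcpp::export]]
NumericVector rng_normals_cpp(int n, double seed) {
  fcrng::Xoshiro256pp rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = fcrng::zigg.draw(rng);
  return out;
}
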