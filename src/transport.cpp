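// Multigroup Monte-Carlo neutron/photon transport engine for axisymmetric
// collimator + phantom scenes.
//
// Geometry: ordered region list (first match wins), world = air, escape at
// the world box. Neutrons: analog capture/scatter with group-to-group
// transfer and isotropic lab-frame scattering; hydrogen capture emits a
// 2.22 MeV photon. Photons: straight-line exponential attenuation, death at
// first collision; dose comes from the track-length energy-fluence tally.
// Tallies: track-length estimators on cylindrical (r,z), voxel and sphere
// meshes, with batch-based relative errors.
//
// RNG: xoshiro256++ seeded through splitmix64 (bit-identical runs for a
// given seed, independent of the R session RNG).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double kInf = std::numeric_limits<double>::infinity();
static const double kEps = 1e-9;    // minimum accepted boundary distance
static const double kNudge = 1e-7;  // post-crossing nudge (cm)

// ---------------------------------------------------------------------------
// RNG
// ---------------------------------------------------------------------------

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0,1)
  inline double u01() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// ---------------------------------------------------------------------------
// Scene
// ---------------------------------------------------------------------------

struct Region {
  int type;       // 1 cone shell, 2 cylinder, 3 box, 4 voxel grid
  int mat;        // 0-based material index (unused for type 4)
  std::vector<double> par;
  // voxel grid only:
  const int* labels = nullptr;
  int nx = 0, ny = 0, nz = 0;
  double ox = 0, oy = 0, oz = 0, h = 0;
  std::vector<int> lab2mat;  // 0-based material per label value (1-based labels)
};

struct Materials {
  int M, G;
  std::vector<double> st, sa, sc;  // st,sa: M*G ; sc: M*G*G (from g to gp)
  std::vector<double> mu, ppa, capE;
  inline double ST(int m, int g) const { return st[m * G + g]; }
  inline double SA(int m, int g) const { return sa[m * G + g]; }
  inline double SC(int m, int g, int gp) const { return sc[(m * G + g) * G + gp]; }
};

struct Scene {
  Materials mats;
  std::vector<Region> regions;
  int air;  // 0-based
  double wlo[3], whi[3];
};

static inline double cone_rin(const std::vector<double>& par, double z) {
  // par: z0 z1 Rout nk z1 r1 z2 r2 ...
  int nk = (int)par[3];
  const double* kz = &par[4];
  if (z <= kz[0]) return kz[1];
  for (int i = 0; i < nk - 1; ++i) {
    double za = kz[2 * i], ra = kz[2 * i + 1];
    double zb = kz[2 * (i + 1)], rb = kz[2 * (i + 1) + 1];
    if (z <= zb) {
      if (zb - za <= 0) return rb;
      double f = (z - za) / (zb - za);
      return ra + f * (rb - ra);
    }
  }
  return kz[2 * (nk - 1) + 1];
}

static inline bool in_world(const Scene& sc, double x, double y, double z) {
  return x >= sc.wlo[0] && x <= sc.whi[0] && y >= sc.wlo[1] && y <= sc.whi[1] &&
         z >= sc.wlo[2] && z <= sc.whi[2];
}

static int locate_material(const Scene& sc, double x, double y, double z) {
  for (size_t i = 0; i < sc.regions.size(); ++i) {
    const Region& rg = sc.regions[i];
    switch (rg.type) {
      case 1: {  // cone shell
        double z0 = rg.par[0], z1 = rg.par[1], Rout = rg.par[2];
        if (z < z0 || z > z1) break;
        double r2 = x * x + y * y;
        if (r2 > Rout * Rout) break;
        double ri = cone_rin(rg.par, z);
        if (r2 >= ri * ri) return rg.mat;
        break;
      }
      case 2: {  // cylinder
        double z0 = rg.par[0], z1 = rg.par[1], R = rg.par[2];
        if (z >= z0 && z <= z1 && x * x + y * y <= R * R) return rg.mat;
        break;
      }
      case 3: {  // box
        if (x >= rg.par[0] && x <= rg.par[1] && y >= rg.par[2] &&
            y <= rg.par[3] && z >= rg.par[4] && z <= rg.par[5])
          return rg.mat;
        break;
      }
      case 4: {  // voxel grid
        double lx = rg.nx * rg.h, ly = rg.ny * rg.h, lz = rg.nz * rg.h;
        if (x < rg.ox || x > rg.ox + lx || y < rg.oy || y > rg.oy + ly ||
            z < rg.oz || z > rg.oz + lz)
          break;
        int ix = (int)((x - rg.ox) / rg.h); if (ix < 0) ix = 0; if (ix >= rg.nx) ix = rg.nx - 1;
        int iy = (int)((y - rg.oy) / rg.h); if (iy < 0) iy = 0; if (iy >= rg.ny) iy = rg.ny - 1;
        int iz = (int)((z - rg.oz) / rg.h); if (iz < 0) iz = 0; if (iz >= rg.nz) iz = rg.nz - 1;
        int lab = rg.labels[ix + rg.nx * (iy + rg.ny * (size_t)iz)];
        return rg.lab2mat[lab - 1];
      }
    }
  }
  return sc.air;
}

static inline void cand_plane(double pz, double dz, double zp, double& tmin) {
  if (std::fabs(dz) < 1e-14) return;
  double t = (zp - pz) / dz;
  if (t > kEps && t < tmin) tmin = t;
}

// quadratic surface x^2+y^2 = (A + B z)^2 restricted to z in [za,zb]
static void cand_cone(const double p[3], const double d[3], double A, double B,
                      double za, double zb, double& tmin) {
  double qa = d[0] * d[0] + d[1] * d[1] - B * B * d[2] * d[2];
  double g0 = A + B * p[2];
  double qb = 2.0 * (p[0] * d[0] + p[1] * d[1] - B * d[2] * g0);
  double qc = p[0] * p[0] + p[1] * p[1] - g0 * g0;
  double roots[2]; int nr = 0;
  if (std::fabs(qa) < 1e-14) {
    if (std::fabs(qb) > 1e-14) roots[nr++] = -qc / qb;
  } else {
    double disc = qb * qb - 4 * qa * qc;
    if (disc >= 0) {
      double sq = std::sqrt(disc);
      roots[nr++] = (-qb - sq) / (2 * qa);
      roots[nr++] = (-qb + sq) / (2 * qa);
    }
  }
  for (int i = 0; i < nr; ++i) {
    double t = roots[i];
    if (t <= kEps || t >= tmin) continue;
    double z = p[2] + t * d[2];
    if (z < za - 1e-12 || z > zb + 1e-12) continue;
    if (A + B * z < -1e-12) continue;  // mirror nappe
    tmin = t;
  }
}

// distance to the next material-relevant boundary; returns +Inf if none
static double distance_boundary(const Scene& sc, const double p[3],
                                const double d[3]) {
  double tmin = kInf;
  // world box
  for (int a = 0; a < 3; ++a) {
    cand_plane(p[a], d[a], sc.wlo[a], tmin);
    cand_plane(p[a], d[a], sc.whi[a], tmin);
  }
  for (size_t i = 0; i < sc.regions.size(); ++i) {
    const Region& rg = sc.regions[i];
    switch (rg.type) {
      case 1: {
        double z0 = rg.par[0], z1 = rg.par[1], Rout = rg.par[2];
        cand_plane(p[2], d[2], z0, tmin);
        cand_plane(p[2], d[2], z1, tmin);
        cand_cone(p, d, Rout, 0.0, z0, z1, tmin);  // outer cylinder
        int nk = (int)rg.par[3];
        const double* kz = &rg.par[4];
        for (int s = 0; s < nk - 1; ++s) {
          double za = kz[2 * s], ra = kz[2 * s + 1];
          double zb = kz[2 * (s + 1)], rb = kz[2 * (s + 1) + 1];
          if (zb - za <= 0) continue;
          double B = (rb - ra) / (zb - za);
          double A = ra - B * za;
          cand_cone(p, d, A, B, za, zb, tmin);
        }
        break;
      }
      case 2: {
        cand_plane(p[2], d[2], rg.par[0], tmin);
        cand_plane(p[2], d[2], rg.par[1], tmin);
        cand_cone(p, d, rg.par[2], 0.0, rg.par[0], rg.par[1], tmin);
        break;
      }
      case 3: {
        for (int a = 0; a < 3; ++a) {
          cand_plane(p[a], d[a], rg.par[2 * a], tmin);
          cand_plane(p[a], d[a], rg.par[2 * a + 1], tmin);
        }
        break;
      }
      case 4: {
        double lo[3] = {rg.ox, rg.oy, rg.oz};
        double hi[3] = {rg.ox + rg.nx * rg.h, rg.oy + rg.ny * rg.h,
                        rg.oz + rg.nz * rg.h};
        bool inside = p[0] > lo[0] && p[0] < hi[0] && p[1] > lo[1] &&
                      p[1] < hi[1] && p[2] > lo[2] && p[2] < hi[2];
        if (inside) {
          // next voxel face along the ray
          for (int a = 0; a < 3; ++a) {
            if (std::fabs(d[a]) < 1e-14) continue;
            double rel = (p[a] - lo[a]) / rg.h;
            double face = d[a] > 0 ? (std::floor(rel) + 1.0) : std::floor(rel);
            double t = (lo[a] + face * rg.h - p[a]) / d[a];
            if (t <= kEps) {  // sitting on a face; take the following one
              t = (lo[a] + (face + (d[a] > 0 ? 1.0 : -1.0)) * rg.h - p[a]) / d[a];
            }
            if (t > kEps && t < tmin) tmin = t;
          }
        } else {
          for (int a = 0; a < 3; ++a) {
            cand_plane(p[a], d[a], lo[a], tmin);
            cand_plane(p[a], d[a], hi[a], tmin);
          }
        }
        break;
      }
    }
  }
  return tmin;
}

static Scene build_scene(const List& engine) {
  Scene sc;
  NumericMatrix st = engine["mat_st"], sa = engine["mat_sa"],
                scm = engine["mat_sc"];
  NumericVector mu = engine["mat_mu"], ppa = engine["mat_ppa"],
                capE = engine["mat_capE"];
  int M = st.nrow(), G = st.ncol();
  sc.mats.M = M; sc.mats.G = G;
  sc.mats.st.resize(M * G); sc.mats.sa.resize(M * G);
  sc.mats.sc.resize(M * G * G);
  for (int m = 0; m < M; ++m)
    for (int g = 0; g < G; ++g) {
      sc.mats.st[m * G + g] = st(m, g);
      sc.mats.sa[m * G + g] = sa(m, g);
      for (int gp = 0; gp < G; ++gp)
        sc.mats.sc[(m * G + g) * G + gp] = scm(m, g * G + gp);
    }
  sc.mats.mu.assign(mu.begin(), mu.end());
  sc.mats.ppa.assign(ppa.begin(), ppa.end());
  sc.mats.capE.assign(capE.begin(), capE.end());
  sc.air = as<int>(engine["air_index"]) - 1;
  NumericVector w = engine["world"];
  sc.wlo[0] = w[0]; sc.whi[0] = w[1]; sc.wlo[1] = w[2]; sc.whi[1] = w[3];
  sc.wlo[2] = w[4]; sc.whi[2] = w[5];
  List regions = engine["regions"];
  for (int i = 0; i < regions.size(); ++i) {
    List rl = regions[i];
    Region rg;
    rg.type = as<int>(rl["type"]);
    if (rg.type == 4) {
      IntegerVector labels = rl["labels"];
      IntegerVector dims = rl["dims"];
      NumericVector origin = rl["origin"];
      IntegerVector l2m = rl["lab2mat"];
      rg.labels = labels.begin();
      rg.nx = dims[0]; rg.ny = dims[1]; rg.nz = dims[2];
      rg.ox = origin[0]; rg.oy = origin[1]; rg.oz = origin[2];
      rg.h = as<double>(rl["h"]);
      rg.lab2mat.resize(l2m.size());
      for (int k = 0; k < l2m.size(); ++k) rg.lab2mat[k] = l2m[k] - 1;
      rg.mat = sc.air;
    } else {
      rg.mat = as<int>(rl["mat"]) - 1;
      NumericVector par = rl["params"];
      rg.par.assign(par.begin(), par.end());
    }
    sc.regions.push_back(rg);
  }
  return sc;
}

// ---------------------------------------------------------------------------
// Tallies
// ---------------------------------------------------------------------------

struct Tally {
  int type;  // 1 cyl, 2 voxel, 3 spheres
  // cyl: z0, dz, nz, dr, nr  | voxel: origin, h, dims | spheres: centers, rs
  double z0 = 0, dz = 0, dr = 0, h = 0, rs = 0;
  double ox = 0, oy = 0, oz = 0;
  int nz = 0, nr = 0, nx = 0, ny = 0;
  std::vector<double> cx, cy, cz;  // sphere centers
  double step = 0.1;
  size_t nb = 0;   // spatial bins
  int nch = 0;     // channels = G + 1
  std::vector<double> cur, sum, ssq;
  double zmin() const { return z0; }
  double zmax() const { return z0 + nz * dz; }
};

static inline void clip_axis(double p, double d, double lo, double hi,
                             double& t0, double& t1) {
  if (std::fabs(d) < 1e-14) {
    if (p < lo || p > hi) { t0 = 1; t1 = 0; }
    return;
  }
  double ta = (lo - p) / d, tb = (hi - p) / d;
  if (ta > tb) std::swap(ta, tb);
  if (ta > t0) t0 = ta;
  if (tb < t1) t1 = tb;
}

static void score_segment(std::vector<Tally>& tallies, const double p[3],
                          const double d[3], double L, double w, int ch) {
  if (L <= 0) return;
  for (size_t it = 0; it < tallies.size(); ++it) {
    Tally& T = tallies[it];
    double* cur = T.cur.data() + (size_t)ch * T.nb;
    if (T.type == 1) {
      double t0 = 0, t1 = L;
      clip_axis(p[2], d[2], T.zmin(), T.zmax(), t0, t1);
      if (t1 <= t0) continue;
      int n = (int)std::ceil((t1 - t0) / T.step);
      double dl = (t1 - t0) / n;
      double rmax = T.nr * T.dr;
      for (int k = 0; k < n; ++k) {
        double t = t0 + (k + 0.5) * dl;
        double x = p[0] + t * d[0], y = p[1] + t * d[1], z = p[2] + t * d[2];
        double r = std::sqrt(x * x + y * y);
        if (r >= rmax) continue;
        int iz = (int)((z - T.z0) / T.dz);
        if (iz < 0 || iz >= T.nz) continue;
        int ir = (int)(r / T.dr);
        cur[(size_t)iz * T.nr + ir] += w * dl;
      }
    } else if (T.type == 2) {
      double t0 = 0, t1 = L;
      clip_axis(p[0], d[0], T.ox, T.ox + T.nx * T.h, t0, t1);
      clip_axis(p[1], d[1], T.oy, T.oy + T.ny * T.h, t0, t1);
      clip_axis(p[2], d[2], T.oz, T.oz + T.nz * T.h, t0, t1);
      if (t1 <= t0) continue;
      int n = (int)std::ceil((t1 - t0) / T.step);
      double dl = (t1 - t0) / n;
      for (int k = 0; k < n; ++k) {
        double t = t0 + (k + 0.5) * dl;
        int ix = (int)((p[0] + t * d[0] - T.ox) / T.h);
        int iy = (int)((p[1] + t * d[1] - T.oy) / T.h);
        int iz = (int)((p[2] + t * d[2] - T.oz) / T.h);
        if (ix < 0 || ix >= T.nx || iy < 0 || iy >= T.ny || iz < 0 || iz >= T.nz)
          continue;
        cur[ix + (size_t)T.nx * (iy + (size_t)T.ny * iz)] += w * dl;
      }
    } else {
      for (size_t s = 0; s < T.cx.size(); ++s) {
        double px = p[0] - T.cx[s], py = p[1] - T.cy[s], pz = p[2] - T.cz[s];
        double b = 2.0 * (px * d[0] + py * d[1] + pz * d[2]);
        double c = px * px + py * py + pz * pz - T.rs * T.rs;
        double disc = b * b - 4 * c;
        if (disc <= 0) continue;
        double sq = std::sqrt(disc);
        double ta = (-b - sq) / 2, tb = (-b + sq) / 2;
        double ov = std::min(L, tb) - std::max(0.0, ta);
        if (ov > 0) cur[s] += w * ov;
      }
    }
  }
}

static std::vector<Tally> build_tallies(const List& specs, int G) {
  std::vector<Tally> out;
  for (int i = 0; i < specs.size(); ++i) {
    List sp = specs[i];
    Tally T;
    T.type = as<int>(sp["type"]);
    T.nch = G + 1;
    if (T.type == 1) {
      T.z0 = as<double>(sp["z0"]); T.dz = as<double>(sp["dz"]);
      T.nz = as<int>(sp["nz"]); T.dr = as<double>(sp["dr"]);
      T.nr = as<int>(sp["nr"]);
      T.nb = (size_t)T.nr * T.nz;
      T.step = 0.5 * std::min(T.dz, T.dr);
    } else if (T.type == 2) {
      NumericVector origin = sp["origin"];
      IntegerVector dims = sp["dims"];
      T.ox = origin[0]; T.oy = origin[1]; T.oz = origin[2];
      T.h = as<double>(sp["h"]);
      T.nx = dims[0]; T.ny = dims[1]; T.nz = dims[2];
      T.nb = (size_t)T.nx * T.ny * T.nz;
      T.step = 0.5 * T.h;
    } else {
      NumericMatrix cen = sp["centers"];
      T.rs = as<double>(sp["radius"]);
      for (int s = 0; s < cen.nrow(); ++s) {
        T.cx.push_back(cen(s, 0)); T.cy.push_back(cen(s, 1));
        T.cz.push_back(cen(s, 2));
      }
      T.nb = T.cx.size();
    }
    T.cur.assign(T.nb * T.nch, 0.0);
    T.sum.assign(T.nb * T.nch, 0.0);
    T.ssq.assign(T.nb * T.nch, 0.0);
    out.push_back(std::move(T));
  }
  return out;
}

// ---------------------------------------------------------------------------
// Source
// ---------------------------------------------------------------------------

struct Source {
  double radius, nexp, photon_fraction, photonE;
  std::vector<double> spectrum;
};

struct Particle {
  int species;  // 0 neutron, 1 photon
  double p[3], d[3];
  int g;        // neutron group (0-based); -1 for photon
  double E;     // photon energy (MeV)
  double w;
};

static void iso_direction(Xoshiro& rng, double d[3]) {
  double mu = 2.0 * rng.u01() - 1.0;
  double phi = 2.0 * M_PI * rng.u01();
  double s = std::sqrt(std::max(0.0, 1.0 - mu * mu));
  d[0] = s * std::cos(phi); d[1] = s * std::sin(phi); d[2] = mu;
}

static Particle sample_primary(const Source& src, Xoshiro& rng) {
  Particle pt;
  double r = src.radius * std::sqrt(rng.u01());
  double phi = 2.0 * M_PI * rng.u01();
  pt.p[0] = r * std::cos(phi); pt.p[1] = r * std::sin(phi); pt.p[2] = 0.0;
  double mu = std::pow(rng.u01(), 1.0 / (src.nexp + 1.0));
  double phid = 2.0 * M_PI * rng.u01();
  double s = std::sqrt(std::max(0.0, 1.0 - mu * mu));
  pt.d[0] = s * std::cos(phid); pt.d[1] = s * std::sin(phid); pt.d[2] = mu;
  pt.w = 1.0;
  if (rng.u01() < src.photon_fraction) {
    pt.species = 1; pt.g = -1; pt.E = src.photonE;
  } else {
    pt.species = 0; pt.E = 0;
    double u = rng.u01(), cum = 0;
    pt.g = (int)src.spectrum.size() - 1;
    for (size_t g = 0; g < src.spectrum.size(); ++g) {
      cum += src.spectrum[g];
      if (u <= cum) { pt.g = (int)g; break; }
    }
  }
  return pt;
}

static Source parse_source(const List& sl) {
  Source src;
  src.radius = as<double>(sl["diskRadius"]);
  src.nexp = as<double>(sl["angularExponent"]);
  src.photon_fraction = as<double>(sl["photonFraction"]);
  src.photonE = as<double>(sl["photonEnergy"]);
  NumericVector sp = sl["groupSpectrum"];
  src.spectrum.assign(sp.begin(), sp.end());
  return src;
}

// ---------------------------------------------------------------------------
// Exported helpers
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_locate(List engine, NumericMatrix pts) {
  Scene sc = build_scene(engine);
  IntegerVector out(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i)
    out[i] = locate_material(sc, pts(i, 0), pts(i, 1), pts(i, 2)) + 1;
  return out;
}

// [[Rcpp::export]]
List cpp_distance(List engine, NumericVector p, NumericVector d) {
  Scene sc = build_scene(engine);
  double pp[3] = {p[0], p[1], p[2]}, dd[3] = {d[0], d[1], d[2]};
  double t = distance_boundary(sc, pp, dd);
  if (!std::isfinite(t))
    return List::create(_["dist"] = R_PosInf, _["mat"] = 0);
  double q[3] = {pp[0] + (t + kNudge) * dd[0], pp[1] + (t + kNudge) * dd[1],
                 pp[2] + (t + kNudge) * dd[2]};
  int mat;
  if (!in_world(sc, q[0], q[1], q[2])) mat = 0;  // escape sentinel
  else mat = locate_material(sc, q[0], q[1], q[2]) + 1;
  return List::create(_["dist"] = t, _["mat"] = mat);
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_source(List source, int n, double seed) {
  Source src = parse_source(source);
  Xoshiro rng((uint64_t)seed);
  NumericMatrix out(n, 9);
  for (int i = 0; i < n; ++i) {
    Particle pt = sample_primary(src, rng);
    out(i, 0) = pt.species;
    out(i, 1) = pt.p[0]; out(i, 2) = pt.p[1]; out(i, 3) = pt.p[2];
    out(i, 4) = pt.d[0]; out(i, 5) = pt.d[1]; out(i, 6) = pt.d[2];
    out(i, 7) = pt.species == 0 ? pt.g + 1 : NA_REAL;
    out(i, 8) = pt.E;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Main run
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run(List engine, List source, List config, List tally_specs) {
  Scene sc = build_scene(engine);
  Source src = parse_source(source);
  int G = sc.mats.G;
  std::vector<Tally> tallies = build_tallies(tally_specs, G);

  double seed = as<double>(config["seed"]);
  int batches = as<int>(config["batches"]);
  long hb = as<double>(config["nHistories"]) / batches;
  if (hb < 1) hb = 1;
  double wcut = as<double>(config["weightCutoff"]);
  double wsur = as<double>(config["rouletteSurvival"]);
  Xoshiro rng((uint64_t)seed);

  long double emitted = 0, secondary = 0, absorbed = 0, escaped = 0;
  long double rkill = 0, rgain = 0;
  const long max_steps = 1000000;

  std::vector<Particle> stack;
  for (int b = 0; b < batches; ++b) {
    for (long hidx = 0; hidx < hb; ++hidx) {
      stack.clear();
      stack.push_back(sample_primary(src, rng));
      emitted += stack.back().w;
      while (!stack.empty()) {
        Particle pt = stack.back();
        stack.pop_back();
        long steps = 0;
        while (true) {
          if (++steps > max_steps) { escaped += pt.w; break; }
          if (!in_world(sc, pt.p[0], pt.p[1], pt.p[2])) {
            escaped += pt.w;
            break;
          }
          int m = locate_material(sc, pt.p[0], pt.p[1], pt.p[2]);
          double sig = pt.species == 0 ? sc.mats.ST(m, pt.g) : sc.mats.mu[m];
          double s = sig > 0 ? -std::log(rng.u01()) / sig : kInf;
          double db = distance_boundary(sc, pt.p, pt.d);
          if (!std::isfinite(s) && !std::isfinite(db)) {  // stuck in void
            escaped += pt.w;
            break;
          }
          double L = std::min(s, db);
          int ch = pt.species == 0 ? pt.g : G;
          double w = pt.species == 0 ? pt.w : pt.w * pt.E;
          score_segment(tallies, pt.p, pt.d, L, w, ch);
          if (s < db) {
            // collision
            for (int a = 0; a < 3; ++a) pt.p[a] += s * pt.d[a];
            if (pt.species == 1) {  // photon: local KERMA deposition
              absorbed += pt.w;
              break;
            }
            double st = sc.mats.ST(m, pt.g), sa = sc.mats.SA(m, pt.g);
            if (rng.u01() < sa / st) {
              absorbed += pt.w;
              if (sc.mats.ppa[m] > 0 && rng.u01() < sc.mats.ppa[m]) {
                Particle ph;
                ph.species = 1; ph.g = -1; ph.E = sc.mats.capE[m];
                ph.w = pt.w;
                for (int a = 0; a < 3; ++a) ph.p[a] = pt.p[a];
                iso_direction(rng, ph.d);
                stack.push_back(ph);
                secondary += ph.w;
              }
              break;
            }
            // scatter: new group from the transfer row, isotropic direction
            double ss = st - sa;
            double u = rng.u01() * ss, cum = 0;
            int gp = G - 1;
            for (int gg = 0; gg < G; ++gg) {
              cum += sc.mats.SC(m, pt.g, gg);
              if (u <= cum) { gp = gg; break; }
            }
            pt.g = gp;
            iso_direction(rng, pt.d);
            // weight cutoff + Russian roulette (no-op for analog weights)
            if (pt.w < wcut) {
              if (rng.u01() < pt.w / wsur) {
                rgain += wsur - pt.w;
                pt.w = wsur;
              } else {
                rkill += pt.w;
                break;
              }
            }
          } else {
            for (int a = 0; a < 3; ++a) pt.p[a] += (db + kNudge) * pt.d[a];
          }
        }
      }
    }
    // fold the finished batch into the running moments
    for (size_t it = 0; it < tallies.size(); ++it) {
      Tally& T = tallies[it];
      for (size_t k = 0; k < T.cur.size(); ++k) {
        double bm = T.cur[k] / hb;
        T.sum[k] += bm;
        T.ssq[k] += bm * bm;
        T.cur[k] = 0.0;
      }
    }
    Rcpp::checkUserInterrupt();
  }

  // assemble results
  List tally_out(tallies.size());
  for (size_t it = 0; it < tallies.size(); ++it) {
    Tally& T = tallies[it];
    size_t n = T.nb * T.nch;
    NumericVector mean(n), relerr(n);
    for (size_t k = 0; k < n; ++k) {
      double m = T.sum[k] / batches;
      double re = NA_REAL;
      if (batches >= 2 && m > 0) {
        double var = (T.ssq[k] - T.sum[k] * T.sum[k] / batches) / (batches - 1);
        re = std::sqrt(std::max(0.0, var) / batches) / m;
      } else if (m == 0) {
        re = NA_REAL;  // zero-mean bin flagged undefined
      }
      mean[k] = m;
      relerr[k] = re;
    }
    // divide by bin volume -> per-source-particle flux / energy fluence
    if (T.type == 1) {
      for (int ch = 0; ch < T.nch; ++ch)
        for (int iz = 0; iz < T.nz; ++iz)
          for (int ir = 0; ir < T.nr; ++ir) {
            double vol = M_PI * ((ir + 1.0) * (ir + 1.0) - (double)ir * ir) *
                         T.dr * T.dr * T.dz;
            mean[(size_t)ch * T.nb + (size_t)iz * T.nr + ir] /= vol;
          }
    } else if (T.type == 2) {
      double vol = T.h * T.h * T.h;
      for (size_t k = 0; k < n; ++k) mean[k] /= vol;
    } else {
      double vol = 4.0 / 3.0 * M_PI * T.rs * T.rs * T.rs;
      for (size_t k = 0; k < n; ++k) mean[k] /= vol;
    }
    tally_out[it] = List::create(_["mean"] = mean, _["relerr"] = relerr);
  }

  double emitted_d = (double)(emitted + secondary);
  double balance = emitted_d - (double)(absorbed + escaped + rkill - rgain);
  NumericVector summary = NumericVector::create(
      _["nHistories"] = (double)hb * batches, _["batches"] = (double)batches,
      _["seed"] = seed, _["emitted"] = (double)emitted,
      _["secondary"] = (double)secondary, _["absorbed"] = (double)absorbed,
      _["escaped"] = (double)escaped, _["rouletteKilled"] = (double)rkill,
      _["rouletteGained"] = (double)rgain, _["balance"] = balance);
  return List::create(_["tallies"] = tally_out, _["summary"] = summary);
}
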