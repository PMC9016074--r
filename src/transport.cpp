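// Monte Carlo photon-packet transport core: layered (MCML-style) and
// voxelated kernels with pluggable RNGs, lookup-table phase-function
// sampling, selectable stepping methods (AW/AR/MBL), surface layouts,
// surface detectors, volumetric deposition and event traces.
//
// All lengths are metres, all coefficients 1/m. Coordinate convention:
// z increases downward into the sample, the top surface is z = 0.
// Transport state and accumulators are double precision; counters are
// 64-bit (stored as doubles on return, exact below 2^53).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <cstdlib>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ----------------------------------------------------------------------
// RNG streams
// ----------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// default generator: xoshiro256++ (public-domain algorithm of Blackman &
// Vigna), seeded through splitmix64; 53-bit uniform doubles in [0, 1)
struct Xoshiro256pp {
  uint64_t s[4];
  void seed(uint64_t sd) {
    uint64_t st = sd;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(st);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// ran3: the lagged subtractive generator of Numerical Recipes in C, as used
// by the original multilayered MC code; shipped for RNG-bias experiments
struct Ran3 {
  long ma[56];
  int inext, inextp;
  void seed(long idum) {
    const long MBIG = 1000000000L, MSEED = 161803398L;
    long mj = std::labs(MSEED - std::labs(idum)) % MBIG;
    ma[55] = mj;
    long mk = 1;
    for (int i = 1; i <= 54; ++i) {
      int ii = (21 * i) % 55;
      ma[ii] = mk;
      mk = mj - mk;
      if (mk < 0) mk += MBIG;
      mj = ma[ii];
    }
    for (int k = 1; k <= 4; ++k)
      for (int i = 1; i <= 55; ++i) {
        ma[i] -= ma[1 + (i + 30) % 55];
        if (ma[i] < 0) ma[i] += MBIG;
      }
    inext = 0; inextp = 31;
  }
  inline double unif() {
    if (++inext == 56) inext = 1;
    if (++inextp == 56) inextp = 1;
    long mj = ma[inext] - ma[inextp];
    if (mj < 0) mj += 1000000000L;
    ma[inext] = mj;
    return mj * 1.0e-9;
  }
};

struct Rng {
  int kind;  // 0 = xoshiro256++, 1 = ran3
  Xoshiro256pp xo;
  Ran3 r3;
  void seed(double sd) {
    if (kind == 1) r3.seed((long)sd);
    else xo.seed((uint64_t)sd);
  }
  inline double unif() { return kind == 1 ? r3.unif() : xo.unif(); }
  // exponential dimensionless step; guards against log(0)
  inline double expstep() { return -std::log1p(-unif()); }
  inline double normal() {  // Box-Muller (one branch; fine for launch use)
    double u1 = unif(), u2 = unif();
    while (u1 <= 0) u1 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

// [[Rcpp::export]]
NumericVector cpp_rng_uniform(int n, int kind, double seed) {
  Rng rng; rng.kind = kind; rng.seed(seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.unif();
  return out;
}

// ----------------------------------------------------------------------
// Shared pieces
// ----------------------------------------------------------------------

struct FresnelResult { double R; double cos_t; bool tir; };

static inline FresnelResult fresnelR(double n1, double n2, double cos_i) {
  FresnelResult f;
  if (n1 == n2) { f.R = 0.0; f.cos_t = cos_i; f.tir = false; return f; }
  double sin_i2 = 1.0 - cos_i * cos_i;
  if (sin_i2 < 0) sin_i2 = 0;
  double sin_t2 = (n1 / n2) * (n1 / n2) * sin_i2;
  if (sin_t2 >= 1.0) { f.R = 1.0; f.cos_t = 0.0; f.tir = true; return f; }
  double cos_t = std::sqrt(1.0 - sin_t2);
  double R;
  if (cos_i > 1.0 - 1e-12) {
    double r0 = (n1 - n2) / (n1 + n2);
    R = r0 * r0;
  } else {
    double rs = (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t);
    double rp = (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i);
    R = 0.5 * (rs * rs + rp * rp);
  }
  f.R = R < 0 ? 0 : (R > 1 ? 1 : R);
  f.cos_t = cos_t; f.tir = false;
  return f;
}

// MCML direction update: rotate by deflection cos_t (= cos theta) and
// azimuth phi about the current direction, with the stable branch near
// vertical propagation
static inline void spin(double &ux, double &uy, double &uz,
                        double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cosp = std::cos(phi), sinp = std::sin(phi);
  double nx, ny, nz;
  if (std::fabs(uz) > 0.99999) {
    nx = sint * cosp;
    ny = sint * sinp;
    nz = cost * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double tmp = std::sqrt(1.0 - uz * uz);
    nx = sint * (ux * uz * cosp - uy * sinp) / tmp + ux * cost;
    ny = sint * (uy * uz * cosp + ux * sinp) / tmp + uy * cost;
    nz = -sint * cosp * tmp + uz * cost;
  }
  double nrm = std::sqrt(nx * nx + ny * ny + nz * nz);
  ux = nx / nrm; uy = ny / nrm; uz = nz / nrm;
}

// [[Rcpp::export]]
NumericVector cpp_scatter_direction(NumericVector dir, double cos_theta,
                                    double phi) {
  double ux = dir[0], uy = dir[1], uz = dir[2];
  spin(ux, uy, uz, cos_theta, phi);
  return NumericVector::create(ux, uy, uz);
}

// Phase-function LUT: inverse-CDF tables, linear interpolation
struct Lut {
  std::vector<double> ct;
  inline double sample(double xi) const {
    double t = xi * (ct.size() - 1);
    int i = (int)t;
    if (i >= (int)ct.size() - 1) i = (int)ct.size() - 2;
    double f = t - i;
    return ct[i] * (1.0 - f) + ct[i + 1] * f;
  }
};

// ----------------------------------------------------------------------
// Detectors and accumulators
// ----------------------------------------------------------------------

struct RadialDet {
  bool present = false;
  std::vector<double> edges, raw;
  double cos_min = 0.0, discarded = 0.0, overflow = 0.0;
  void init(List cfg) {
    present = true;
    edges = as<std::vector<double>>(cfg["edges"]);
    cos_min = as<double>(cfg["cos_min"]);
    raw.assign(edges.size() - 1, 0.0);
  }
  void score(double x, double y, double cos_exit, double w) {
    if (!present) return;
    if (cos_exit < cos_min) { discarded += w; return; }
    double r = std::sqrt(x * x + y * y);
    // half-open bins [lo, hi); last upper edge inclusive
    if (r < edges.front() || r > edges.back()) { overflow += w; return; }
    size_t lo = 0, hi = edges.size() - 1;
    while (hi - lo > 1) {
      size_t mid = (lo + hi) / 2;
      if (r < edges[mid]) hi = mid; else lo = mid;
    }
    if (lo >= raw.size()) lo = raw.size() - 1;
    raw[lo] += w;
  }
};

struct CartDet {
  bool present = false;
  double x0, dx, y0, dy;
  int nx, ny;
  double cos_min = 0.0;
  double ax, ay, az;  // acceptance axis (unit, pointing out of the surface)
  std::vector<double> raw;
  double discarded = 0.0, overflow = 0.0;
  void init(List cfg, bool top) {
    present = true;
    x0 = as<double>(cfg["x0"]); dx = as<double>(cfg["dx"]);
    nx = as<int>(cfg["nx"]);
    y0 = as<double>(cfg["y0"]); dy = as<double>(cfg["dy"]);
    ny = as<int>(cfg["ny"]);
    cos_min = as<double>(cfg["cos_min"]);
    double tilt = as<double>(cfg["tilt"]);  // radians, about the y axis
    // outward normal is -z on top, +z on bottom
    ax = std::sin(tilt); ay = 0.0;
    az = (top ? -1.0 : 1.0) * std::cos(tilt);
    raw.assign((size_t)nx * ny, 0.0);
  }
  void score(double x, double y, double ux, double uy, double uz, double w) {
    if (!present) return;
    double ca = ux * ax + uy * ay + uz * az;
    if (ca < cos_min) { discarded += w; return; }
    int ix = (int)std::floor((x - x0) / dx);
    int iy = (int)std::floor((y - y0) / dy);
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) { overflow += w; return; }
    raw[(size_t)iy * nx + ix] += w;
  }
};

struct FiberDet {
  bool present = false;
  std::vector<double> cx, cy;
  double core_r = 0.0, na = 0.0;
  std::vector<double> raw;
  double discarded = 0.0;
  void init(List cfg) {
    present = true;
    cx = as<std::vector<double>>(cfg["cx"]);
    cy = as<std::vector<double>>(cfg["cy"]);
    core_r = as<double>(cfg["core_radius"]);
    na = as<double>(cfg["na"]);
    raw.assign(cx.size(), 0.0);
  }
  int which_fiber(double x, double y) const {
    for (size_t k = 0; k < cx.size(); ++k) {
      double ddx = x - cx[k], ddy = y - cy[k];
      if (ddx * ddx + ddy * ddy <= core_r * core_r) return (int)k;
    }
    return -1;
  }
  // n_medium: index of the medium the exit direction lives in
  void score(double x, double y, double ux, double uy, double n_medium,
             double w) {
    if (!present) return;
    int k = which_fiber(x, y);
    if (k < 0) return;  // outside every core: not this detector's weight
    double sin_exit = std::sqrt(ux * ux + uy * uy);
    if (sin_exit <= na / n_medium + 1e-9) raw[k] += w;
    else discarded += w;
  }
};

struct Fluence {
  bool present = false;
  double x0, dx, y0, dy, z0, dz;
  int nx, ny, nz;
  std::vector<double> raw;
  double offgrid = 0.0;
  void init(List cfg) {
    present = true;
    x0 = as<double>(cfg["x0"]); dx = as<double>(cfg["dx"]);
    nx = as<int>(cfg["nx"]);
    y0 = as<double>(cfg["y0"]); dy = as<double>(cfg["dy"]);
    ny = as<int>(cfg["ny"]);
    z0 = as<double>(cfg["z0"]); dz = as<double>(cfg["dz"]);
    nz = as<int>(cfg["nz"]);
    raw.assign((size_t)nx * ny * nz, 0.0);
  }
  inline void deposit(double x, double y, double z, double dw) {
    if (!present || dw <= 0) return;
    int ix = (int)std::floor((x - x0) / dx);
    int iy = (int)std::floor((y - y0) / dy);
    int iz = (int)std::floor((z - z0) / dz);
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
      offgrid += dw;
      return;
    }
    raw[((size_t)iz * ny + iy) * nx + ix] += dw;
  }
};

// Event trace buffer. Event types: 0 launch, 1 scatter, 2 refraction /
// boundary interaction, 3 terminal. Per-packet summaries (fate, terminal
// state) are kept for every packet; the event lists can optionally be
// restricted at recording time to packets that terminate inside a
// detector-fiber footprint, which keeps the buffer small enough for
// sampling-volume work at realistic launch counts.
struct Trace {
  bool present = false;
  int capacity = 1000;
  std::vector<int> id, type;
  std::vector<double> x, y, z, ux, uy, uz, w;
  // per-packet summaries
  std::vector<int> fate;       // 0 died, 1 top, 2 bottom, 3 lateral
  std::vector<int> n_events;
  std::vector<int> overflowed; // event count exceeded capacity
  std::vector<double> tx, ty, tz, tux, tuy, tuz, tw;  // terminal state
  int cur_events = 0;
  bool cur_over = false;
  size_t cur_start = 0;
  // recording-time filter (applied at packet termination)
  bool filt = false;
  double fcx = 0, fcy = 0, frad = 0, fna = 1, fnexit = 1;
  void init(List cfg, double n_packets) {
    present = true;
    capacity = as<int>(cfg["capacity"]);
    if (cfg.containsElementNamed("filter") && !Rf_isNull(cfg["filter"])) {
      List fl(cfg["filter"]);
      filt = true;
      fcx = as<double>(fl["cx"]); fcy = as<double>(fl["cy"]);
      frad = as<double>(fl["radius"]);
      fna = as<double>(fl["na"]); fnexit = as<double>(fl["n_exit"]);
    }
    size_t n = (size_t)n_packets;
    fate.assign(n, 0); n_events.assign(n, 0); overflowed.assign(n, 0);
    tx.assign(n, 0); ty.assign(n, 0); tz.assign(n, 0);
    tux.assign(n, 0); tuy.assign(n, 0); tuz.assign(n, 0); tw.assign(n, 0);
  }
  inline void begin_packet() {
    cur_events = 0; cur_over = false; cur_start = id.size();
  }
  inline void event(int pid, int tp, double px, double py, double pz,
                    double dx_, double dy_, double dz_, double pw) {
    if (!present) return;
    if (cur_events >= capacity) { cur_over = true; return; }
    ++cur_events;
    id.push_back(pid); type.push_back(tp);
    x.push_back(px); y.push_back(py); z.push_back(pz);
    ux.push_back(dx_); uy.push_back(dy_); uz.push_back(dz_);
    w.push_back(pw);
  }
  inline void drop_current() {
    id.resize(cur_start); type.resize(cur_start);
    x.resize(cur_start); y.resize(cur_start); z.resize(cur_start);
    ux.resize(cur_start); uy.resize(cur_start); uz.resize(cur_start);
    w.resize(cur_start);
  }
  inline void finish(int pid, int f, double px, double py, double pz,
                     double dx_, double dy_, double dz_, double pw) {
    if (!present) return;
    event(pid, 3, px, py, pz, dx_, dy_, dz_, pw);
    fate[pid] = f; n_events[pid] = cur_events;
    overflowed[pid] = cur_over ? 1 : 0;
    tx[pid] = px; ty[pid] = py; tz[pid] = pz;
    tux[pid] = dx_; tuy[pid] = dy_; tuz[pid] = dz_; tw[pid] = pw;
    if (filt) {
      bool keep = (f == 1) && !cur_over;
      if (keep && frad >= 0) {
        double ddx = px - fcx, ddy = py - fcy;
        keep = ddx * ddx + ddy * ddy <= frad * frad;
      }
      if (keep && fna < 1) {
        double s = std::sqrt(dx_ * dx_ + dy_ * dy_);
        keep = s <= fna / fnexit + 1e-9;
      }
      if (!keep) drop_current();
    }
  }
};

// Surface layout at the top boundary
struct Layout {
  int kind = 0;  // 0 uniform/none, 1 fiber probe
  std::vector<double> cx, cy;
  double core_r = 0, clad_r = 0, n_core = 1, na = 0;
  double tip_r = 0, reflectivity = 0;
  bool lambertian = false;
  void init(List cfg) {
    kind = as<int>(cfg["kind"]);
    if (kind == 1) {
      cx = as<std::vector<double>>(cfg["cx"]);
      cy = as<std::vector<double>>(cfg["cy"]);
      core_r = as<double>(cfg["core_radius"]);
      clad_r = as<double>(cfg["cladding_radius"]);
      n_core = as<double>(cfg["n_core"]);
      na = as<double>(cfg["na"]);
      tip_r = as<double>(cfg["tip_radius"]);
      reflectivity = as<double>(cfg["reflectivity"]);
      lambertian = as<bool>(cfg["lambertian"]);
    }
  }
  int which_core(double x, double y) const {
    for (size_t k = 0; k < cx.size(); ++k) {
      double ddx = x - cx[k], ddy = y - cy[k];
      if (ddx * ddx + ddy * ddy <= core_r * core_r) return (int)k;
    }
    return -1;
  }
};

struct Totals {
  double specular = 0, reflected = 0, transmitted = 0, absorbed = 0;
  double lateral = 0, layout_absorbed = 0;
  double roulette_killed = 0, roulette_boost = 0, cutoff_killed = 0;
  double launched_weight = 0;
  double step_cap_hits = 0;
};

// Common per-run configuration
struct RunCfg {
  double n_packets;
  Rng rng;
  int stepping;            // 0 AW, 1 AR, 2 MBL
  bool roulette;
  double rl_threshold, rl_m;
  double weight_cutoff;    // used when roulette disabled (trace runs)
  long max_steps;
  std::vector<Lut> luts;
  double n_above, n_below;
  Layout layout;
  RadialDet rad_top, rad_bot;
  CartDet cart_top, cart_bot;
  FiberDet fib_top;
  Fluence flu;
  Trace trace;
};

static void parse_common(List cfg, RunCfg &rc) {
  rc.n_packets = as<double>(cfg["n_packets"]);
  rc.rng.kind = as<int>(cfg["rng_kind"]);
  rc.rng.seed(as<double>(cfg["seed"]));
  rc.stepping = as<int>(cfg["stepping"]);
  rc.roulette = as<bool>(cfg["roulette"]);
  rc.rl_threshold = as<double>(cfg["roulette_threshold"]);
  rc.rl_m = as<double>(cfg["roulette_m"]);
  rc.weight_cutoff = as<double>(cfg["weight_cutoff"]);
  rc.max_steps = (long)as<double>(cfg["max_steps"]);
  List luts(cfg["luts"]);
  rc.luts.resize(luts.size());
  for (int i = 0; i < luts.size(); ++i)
    rc.luts[i].ct = as<std::vector<double>>(luts[i]);
  rc.n_above = as<double>(cfg["n_above"]);
  rc.n_below = as<double>(cfg["n_below"]);
  rc.layout.init(List(cfg["layout"]));
  List det(cfg["detectors"]);
  if (det.containsElementNamed("radial_top") &&
      !Rf_isNull(det["radial_top"])) rc.rad_top.init(List(det["radial_top"]));
  if (det.containsElementNamed("radial_bottom") &&
      !Rf_isNull(det["radial_bottom"]))
    rc.rad_bot.init(List(det["radial_bottom"]));
  if (det.containsElementNamed("cartesian_top") &&
      !Rf_isNull(det["cartesian_top"]))
    rc.cart_top.init(List(det["cartesian_top"]), true);
  if (det.containsElementNamed("cartesian_bottom") &&
      !Rf_isNull(det["cartesian_bottom"]))
    rc.cart_bot.init(List(det["cartesian_bottom"]), false);
  if (det.containsElementNamed("fiber_top") &&
      !Rf_isNull(det["fiber_top"])) rc.fib_top.init(List(det["fiber_top"]));
  if (!Rf_isNull(cfg["fluence"])) rc.flu.init(List(cfg["fluence"]));
  if (!Rf_isNull(cfg["trace"]))
    rc.trace.init(List(cfg["trace"]), rc.n_packets);
}

// Source sampling. Returns initial packet state; adds specular weight.
struct Source {
  int kind;  // 0 pencil, 1 isotropic, 2 gaussian, 3 uniform, 4 fiber, 5 rect
  double p1, p2, p3, p4;
  void init(List cfg) {
    kind = as<int>(cfg["kind"]);
    NumericVector pr(cfg["params"]);
    p1 = pr.size() > 0 ? pr[0] : 0;
    p2 = pr.size() > 1 ? pr[1] : 0;
    p3 = pr.size() > 2 ? pr[2] : 0;
    p4 = pr.size() > 3 ? pr[3] : 0;
  }
  // n_entry: refractive index of the medium at the entry point
  void launch(Rng &rng, double n_above, double n_entry,
              double &x, double &y, double &z,
              double &ux, double &uy, double &uz,
              double &wgt, double &spec) const {
    x = y = z = 0; ux = uy = 0; uz = 1; wgt = 1; spec = 0;
    switch (kind) {
    case 1: {  // isotropic point source at (p1, p2, p3) inside the sample
      x = p1; y = p2; z = p3;
      uz = 2.0 * rng.unif() - 1.0;
      double st = std::sqrt(std::max(0.0, 1.0 - uz * uz));
      double phi = 2.0 * M_PI * rng.unif();
      ux = st * std::cos(phi); uy = st * std::sin(phi);
      return;  // no boundary crossing at launch
    }
    case 2: {  // collimated gaussian beam, p1 = FWHM
      double sigma = p1 / 2.3548200450309493;
      x = sigma * rng.normal(); y = sigma * rng.normal();
      break;
    }
    case 3: {  // collimated uniform beam, p1 = radius
      double r = p1 * std::sqrt(rng.unif());
      double phi = 2.0 * M_PI * rng.unif();
      x = r * std::cos(phi); y = r * std::sin(phi);
      break;
    }
    case 5: {  // collimated rectangular source, p1 x p2
      x = (rng.unif() - 0.5) * p1;
      y = (rng.unif() - 0.5) * p2;
      break;
    }
    case 4: {  // optical fiber: p1 core radius, p2 NA (in air), p3 core index
      double r = p1 * std::sqrt(rng.unif());
      double phi = 2.0 * M_PI * rng.unif();
      x = r * std::cos(phi); y = r * std::sin(phi);
      double na = p2, ncore = p3;
      double cmin = std::sqrt(std::max(0.0, 1.0 - na * na));
      double cos_air = cmin + (1.0 - cmin) * rng.unif();
      double sin_air = std::sqrt(std::max(0.0, 1.0 - cos_air * cos_air));
      double sin_core = sin_air / ncore;
      double cos_core = std::sqrt(std::max(0.0, 1.0 - sin_core * sin_core));
      FresnelResult f = fresnelR(ncore, n_entry, cos_core);
      spec = wgt * f.R;
      wgt -= spec;
      double sin_s = ncore * sin_core / n_entry;
      double cos_s = std::sqrt(std::max(0.0, 1.0 - sin_s * sin_s));
      double phi2 = 2.0 * M_PI * rng.unif();
      ux = sin_s * std::cos(phi2); uy = sin_s * std::sin(phi2); uz = cos_s;
      return;
    }
    default: break;  // pencil / line source: (0,0,0) along +z
    }
    // collimated sources cross the surrounding-medium/sample interface
    FresnelResult f = fresnelR(n_above, n_entry, 1.0);
    spec = wgt * f.R;
    wgt -= spec;
  }
};

// [[Rcpp::export]]
NumericMatrix cpp_sample_launch(List source_cfg, int n, double seed,
                                int rng_kind, double n_above, double n_entry) {
  Source src; src.init(source_cfg);
  Rng rng; rng.kind = rng_kind; rng.seed(seed);
  NumericMatrix out(n, 8);
  colnames(out) = CharacterVector::create("x", "y", "z", "ux", "uy", "uz",
                                          "w", "specular");
  for (int i = 0; i < n; ++i) {
    double x, y, z, ux, uy, uz, w, spec;
    src.launch(rng, n_above, n_entry, x, y, z, ux, uy, uz, w, spec);
    out(i, 0) = x; out(i, 1) = y; out(i, 2) = z;
    out(i, 3) = ux; out(i, 4) = uy; out(i, 5) = uz;
    out(i, 6) = w; out(i, 7) = spec;
  }
  return out;
}

// Roulette; returns false when the packet is terminated
static inline bool roulette_or_cutoff(RunCfg &rc, double &w, Totals &tt) {
  if (rc.roulette) {
    if (w >= rc.rl_threshold || w <= 0) return w > 0;
    if (rc.rng.unif() < 1.0 / rc.rl_m) {
      tt.roulette_boost += w * (rc.rl_m - 1.0);
      w *= rc.rl_m;
      return true;
    }
    tt.roulette_killed += w;
    w = 0;
    return false;
  }
  if (w < rc.weight_cutoff) { tt.cutoff_killed += w; w = 0; return false; }
  return w > 0;
}

// ----------------------------------------------------------------------
// Layered kernel
// ----------------------------------------------------------------------

struct Layers {
  std::vector<double> mua, mus, n, ztop, zbot;
  std::vector<int> lut;
  int nlay;
  void init(List cfg) {
    mua = as<std::vector<double>>(cfg["mua"]);
    mus = as<std::vector<double>>(cfg["mus"]);
    n = as<std::vector<double>>(cfg["n"]);
    ztop = as<std::vector<double>>(cfg["z_top"]);
    zbot = as<std::vector<double>>(cfg["z_bottom"]);
    lut = as<std::vector<int>>(cfg["lut"]);
    nlay = (int)mua.size();
  }
};

static List results_common(RunCfg &rc, Totals &tt);

// [[Rcpp::export]]
List cpp_run_layered(List cfg) {
  RunCfg rc;
  parse_common(cfg, rc);
  if (rc.stepping != 0)
    stop("the layered engine supports the Albedo-Weight stepping method");
  Layers ly; ly.init(List(cfg["layers"]));
  Source src; src.init(List(cfg["source"]));
  Totals tt;
  long n = (long)rc.n_packets;

  for (long ip = 0; ip < n; ++ip) {
    double x, y, z, ux, uy, uz, w, spec;
    src.launch(rc.rng, rc.n_above, ly.n[0], x, y, z, ux, uy, uz, w, spec);
    tt.specular += spec;
    tt.launched_weight += w + spec;
    // locate layer (half-open [ztop, zbot))
    int il = 0;
    while (il < ly.nlay - 1 && z >= ly.zbot[il]) ++il;
    rc.trace.begin_packet();
    rc.trace.event((int)ip, 0, x, y, z, ux, uy, uz, w);

    bool alive = true;
    double s = rc.rng.expstep();  // dimensionless step
    long steps = 0;
    while (alive) {
      if (++steps > rc.max_steps) { tt.step_cap_hits += 1; tt.absorbed += w;
        rc.trace.finish((int)ip, 0, x, y, z, ux, uy, uz, 0); break; }
      double mut = ly.mua[il] + ly.mus[il];
      double db;  // distance to the layer boundary along the flight
      int to;     // -1 above, +1 below, 0 none
      if (uz > 0) { db = (ly.zbot[il] - z) / uz; to = 1; }
      else if (uz < 0) { db = (ly.ztop[il] - z) / uz; to = -1; }
      else { db = INF; to = 0; }
      double dfree = (mut > 0) ? s / mut : INF;
      if (dfree >= db) {
        // hop to the boundary, carry the unused dimensionless step
        x += ux * db; y += uy * db; z += uz * db;
        s -= db * mut;
        double n1 = ly.n[il];
        bool top_surface = (to < 0 && il == 0);
        bool bottom_exit = (to > 0 && il == ly.nlay - 1);
        double n2 = top_surface ? rc.n_above
                  : bottom_exit ? rc.n_below
                  : ly.n[il + to];
        double cos_i = std::fabs(uz);

        if (top_surface && rc.layout.kind == 1) {
          // fiber-probe tip layout
          double r2 = x * x + y * y;
          int k = rc.layout.which_core(x, y);
          if (k >= 0) {
            FresnelResult f = fresnelR(n1, rc.layout.n_core, cos_i);
            if (f.tir || rc.rng.unif() < f.R) {
              uz = -uz;
              rc.trace.event((int)ip, 2, x, y, z, ux, uy, uz, w);
            } else {
              // transmitted into the fiber core: escaped through the top
              double scale = n1 / rc.layout.n_core;
              double tux = ux * scale, tuy = uy * scale;
              double tuz = -f.cos_t;
              tt.reflected += w;
              if (rc.fib_top.present)
                rc.fib_top.score(x, y, tux, tuy, rc.layout.n_core, w);
              rc.rad_top.score(x, y, f.cos_t, w);
              rc.cart_top.score(x, y, tux, tuy, tuz, w);
              rc.trace.finish((int)ip, 1, x, y, z, tux, tuy, tuz, w);
              alive = false;
            }
          } else if (r2 <= rc.layout.tip_r * rc.layout.tip_r) {
            // under the probe housing: partial reflection
            tt.layout_absorbed += w * (1.0 - rc.layout.reflectivity);
            w *= rc.layout.reflectivity;
            if (w <= 0) {
              rc.trace.finish((int)ip, 0, x, y, z, ux, uy, uz, 0);
              alive = false;
            } else {
              if (rc.layout.lambertian) {
                double czn = std::sqrt(rc.rng.unif());
                double szn = std::sqrt(std::max(0.0, 1.0 - czn * czn));
                double ph = 2.0 * M_PI * rc.rng.unif();
                ux = szn * std::cos(ph); uy = szn * std::sin(ph); uz = czn;
              } else {
                uz = -uz;
              }
              rc.trace.event((int)ip, 2, x, y, z, ux, uy, uz, w);
              if (!roulette_or_cutoff(rc, w, tt)) {
                rc.trace.finish((int)ip, 0, x, y, z, ux, uy, uz, 0);
                alive = false;
              }
            }
          } else {
            // outside the probe tip: plain boundary optics vs n_above
            FresnelResult f = fresnelR(n1, rc.n_above, cos_i);
            if (f.tir || rc.rng.unif() < f.R) {
              uz = -uz;
              rc.trace.event((int)ip, 2, x, y, z, ux, uy, uz, w);
            } else {
              double scale = n1 / rc.n_above;
              double tux = ux * scale, tuy = uy * scale, tuz = -f.cos_t;
              tt.reflected += w;
              rc.rad_top.score(x, y, f.cos_t, w);
              rc.cart_top.score(x, y, tux, tuy, tuz, w);
              if (rc.fib_top.present)
                rc.fib_top.score(x, y, tux, tuy, rc.n_above, w);
              rc.trace.finish((int)ip, 1, x, y, z, tux, tuy, tuz, w);
              alive = false;
            }
          }
        } else if (top_surface || bottom_exit) {
          FresnelResult f = fresnelR(n1, n2, cos_i);
          if (f.tir || rc.rng.unif() < f.R) {
            uz = -uz;
            rc.trace.event((int)ip, 2, x, y, z, ux, uy, uz, w);
          } else {
            double scale = n1 / n2;
            double tux = ux * scale, tuy = uy * scale;
            double tuz = (to > 0 ? f.cos_t : -f.cos_t);
            if (top_surface) {
              tt.reflected += w;
              rc.rad_top.score(x, y, f.cos_t, w);
              rc.cart_top.score(x, y, tux, tuy, tuz, w);
              if (rc.fib_top.present)
                rc.fib_top.score(x, y, tux, tuy, rc.n_above, w);
              rc.trace.finish((int)ip, 1, x, y, z, tux, tuy, tuz, w);
            } else {
              tt.transmitted += w;
              rc.rad_bot.score(x, y, f.cos_t, w);
              rc.cart_bot.score(x, y, tux, tuy, tuz, w);
              rc.trace.finish((int)ip, 2, x, y, z, tux, tuy, tuz, w);
            }
            alive = false;
          }
        } else {
          // interior interface
          FresnelResult f = fresnelR(n1, n2, cos_i);
          if (f.tir || rc.rng.unif() < f.R) {
            uz = -uz;
          } else {
            double scale = n1 / n2;
            ux *= scale; uy *= scale;
            uz = (uz > 0 ? f.cos_t : -f.cos_t);
            il += to;
          }
          rc.trace.event((int)ip, 2, x, y, z, ux, uy, uz, w);
        }
      } else {
        // extinction event inside the layer
        x += ux * dfree; y += uy * dfree; z += uz * dfree;
        double mua = ly.mua[il];
        if (mut > 0 && mua > 0) {
          double dw = w * mua / mut;
          tt.absorbed += dw;
          rc.flu.deposit(x, y, z, dw);
          w -= dw;
        }
        if (ly.mus[il] <= 0) {
          // pure absorber: no scattering; weight decays until cutoff
          if (!roulette_or_cutoff(rc, w, tt)) {
            rc.trace.finish((int)ip, 0, x, y, z, ux, uy, uz, 0);
            alive = false;
          } else {
            s = rc.rng.expstep();
            rc.trace.event((int)ip, 1, x, y, z, ux, uy, uz, w);
          }
          continue;
        }
        double cost = rc.luts[ly.lut[il]].sample(rc.rng.unif());
        double phi = 2.0 * M_PI * rc.rng.unif();
        spin(ux, uy, uz, cost, phi);
        rc.trace.event((int)ip, 1, x, y, z, ux, uy, uz, w);
        if (!roulette_or_cutoff(rc, w, tt)) {
          rc.trace.finish((int)ip, 0, x, y, z, ux, uy, uz, 0);
          alive = false;
        }
        s = rc.rng.expstep();
      }
    }
  }
  return results_common(rc, tt);
}

// ----------------------------------------------------------------------
// Voxel kernel
// ----------------------------------------------------------------------

struct Volume {
  int nx, ny, nz;
  double x0, y0, z0, dx, dy, dz;
  std::vector<int> labels;               // nx*ny*nz, x fastest
  std::vector<double> mua, mus, n;       // per label
  std::vector<int> lut;
  void init(List cfg) {
    nx = as<int>(cfg["nx"]); ny = as<int>(cfg["ny"]); nz = as<int>(cfg["nz"]);
    x0 = as<double>(cfg["x0"]); y0 = as<double>(cfg["y0"]);
    z0 = as<double>(cfg["z0"]);
    dx = as<double>(cfg["dx"]); dy = as<double>(cfg["dy"]);
    dz = as<double>(cfg["dz"]);
    labels = as<std::vector<int>>(cfg["labels"]);
    mua = as<std::vector<double>>(cfg["mua"]);
    mus = as<std::vector<double>>(cfg["mus"]);
    n = as<std::vector<double>>(cfg["n"]);
    lut = as<std::vector<int>>(cfg["lut"]);
  }
  inline int label_at(int ix, int iy, int iz) const {
    return labels[((size_t)iz * ny + iy) * nx + ix];
  }
};

// [[Rcpp::export]]
List cpp_run_voxel(List cfg) {
  RunCfg rc;
  parse_common(cfg, rc);
  Volume vol; vol.init(List(cfg["volume"]));
  Source src; src.init(List(cfg["source"]));
  Totals tt;
  long n = (long)rc.n_packets;
  const double nudge = 1e-12 * std::min(vol.dx, std::min(vol.dy, vol.dz));
  const int stepping = rc.stepping;  // 0 AW, 1 AR, 2 MBL

  for (long ip = 0; ip < n; ++ip) {
    double x, y, z, ux, uy, uz, w, spec;
    // entry material: voxel at the beam axis, top face
    int eix = std::min(vol.nx - 1, std::max(0, (int)std::floor((0 - vol.x0) / vol.dx)));
    int eiy = std::min(vol.ny - 1, std::max(0, (int)std::floor((0 - vol.y0) / vol.dy)));
    double n_entry = vol.n[vol.label_at(eix, eiy, 0)];
    src.launch(rc.rng, rc.n_above, n_entry, x, y, z, ux, uy, uz, w, spec);
    tt.specular += spec;
    tt.launched_weight += w + spec;

    int ix = (int)std::floor((x - vol.x0) / vol.dx);
    int iy = (int)std::floor((y - vol.y0) / vol.dy);
    int iz = (int)std::floor((z - vol.z0) / vol.dz);
    if (ix < 0 || ix >= vol.nx || iy < 0 || iy >= vol.ny ||
        iz < 0 || iz >= vol.nz) { tt.lateral += w; continue; }

    bool alive = true;
    double s = rc.rng.expstep();
    long steps = 0;
    while (alive) {
      if (++steps > rc.max_steps) { tt.step_cap_hits += 1; tt.absorbed += w;
        break; }
      int lab = vol.label_at(ix, iy, iz);
      double mua = vol.mua[lab], mus = vol.mus[lab];
      double mut = mua + mus;
      // interaction rate that consumes the dimensionless step:
      // AW/AR sample extinction (mua + mus); MBL samples scattering only
      double rate = (stepping == 2) ? mus : mut;
      // distances to the three voxel faces along the flight direction
      double txf = (ux > 0) ? ((vol.x0 + (ix + 1) * vol.dx) - x) / ux
                 : (ux < 0) ? ((vol.x0 + ix * vol.dx) - x) / ux : INF;
      double tyf = (uy > 0) ? ((vol.y0 + (iy + 1) * vol.dy) - y) / uy
                 : (uy < 0) ? ((vol.y0 + iy * vol.dy) - y) / uy : INF;
      double tzf = (uz > 0) ? ((vol.z0 + (iz + 1) * vol.dz) - z) / uz
                 : (uz < 0) ? ((vol.z0 + iz * vol.dz) - z) / uz : INF;
      double dface = std::min(txf, std::min(tyf, tzf));
      if (dface < 0) dface = 0;
      int axis = (dface == txf) ? 0 : (dface == tyf) ? 1 : 2;
      double dfree = (rate > 0) ? s / rate : INF;

      if (dfree < dface) {
        // interaction inside the voxel
        x += ux * dfree; y += uy * dfree; z += uz * dfree;
        if (stepping == 0) {         // Albedo-Weight
          if (mut > 0 && mua > 0) {
            double dw = w * mua / mut;
            tt.absorbed += dw;
            rc.flu.deposit(x, y, z, dw);
            w -= dw;
          }
        } else if (stepping == 1) {  // Albedo-Reject
          if (mut > 0 && rc.rng.unif() < mua / mut) {
            tt.absorbed += w;
            rc.flu.deposit(x, y, z, w);
            w = 0;
            break;
          }
        } else {                     // Microscopic Beer-Lambert
          if (mua > 0) {
            double dw = w * (1.0 - std::exp(-mua * dfree));
            tt.absorbed += dw;
            // deposited along the segment; binned at its midpoint
            rc.flu.deposit(x - 0.5 * dfree * ux, y - 0.5 * dfree * uy,
                           z - 0.5 * dfree * uz, dw);
            w -= dw;
          }
        }
        if (mus <= 0) {  // no scattering possible; should not happen (rate>0)
          s = rc.rng.expstep();
          continue;
        }
        double cost = rc.luts[vol.lut[lab]].sample(rc.rng.unif());
        double phi = 2.0 * M_PI * rc.rng.unif();
        spin(ux, uy, uz, cost, phi);
        if (!roulette_or_cutoff(rc, w, tt)) break;
        s = rc.rng.expstep();
      } else {
        // propagate to the voxel face
        x += ux * dface; y += uy * dface; z += uz * dface;
        if (rate > 0) s -= dface * rate;
        if (stepping == 2 && mua > 0) {
          double dw = w * (1.0 - std::exp(-mua * dface));
          tt.absorbed += dw;
          rc.flu.deposit(x - 0.5 * dface * ux, y - 0.5 * dface * uy,
                         z - 0.5 * dface * uz, dw);
          w -= dw;
          if (!rc.roulette && w < rc.weight_cutoff) {
            tt.cutoff_killed += w; break;
          }
        }
        int step_dir = (axis == 0) ? (ux > 0 ? 1 : -1)
                     : (axis == 1) ? (uy > 0 ? 1 : -1)
                     : (uz > 0 ? 1 : -1);
        int jx = ix + (axis == 0 ? step_dir : 0);
        int jy = iy + (axis == 1 ? step_dir : 0);
        int jz = iz + (axis == 2 ? step_dir : 0);
        bool outside = jx < 0 || jx >= vol.nx || jy < 0 || jy >= vol.ny ||
                       jz < 0 || jz >= vol.nz;
        double n1 = vol.n[lab];
        double n2;
        if (outside) {
          n2 = (axis == 2) ? (jz < 0 ? rc.n_above : rc.n_below) : n1;
        } else {
          n2 = vol.n[vol.label_at(jx, jy, jz)];
        }
        double cos_i = (axis == 0) ? std::fabs(ux)
                     : (axis == 1) ? std::fabs(uy) : std::fabs(uz);
        bool reflectp = false;
        FresnelResult f;
        f.cos_t = cos_i; f.R = 0; f.tir = false;
        if (n1 != n2) {
          f = fresnelR(n1, n2, cos_i);
          reflectp = f.tir || rc.rng.unif() < f.R;
        }
        if (reflectp) {
          if (axis == 0) ux = -ux; else if (axis == 1) uy = -uy; else uz = -uz;
          // nudge back into the current voxel
          x += ux * nudge; y += uy * nudge; z += uz * nudge;
        } else {
          // refract across the face when indices differ
          if (n1 != n2) {
            double scale = n1 / n2;
            if (axis == 0) {
              uy *= scale; uz *= scale;
              ux = (ux > 0 ? f.cos_t : -f.cos_t);
            } else if (axis == 1) {
              ux *= scale; uz *= scale;
              uy = (uy > 0 ? f.cos_t : -f.cos_t);
            } else {
              ux *= scale; uy *= scale;
              uz = (uz > 0 ? f.cos_t : -f.cos_t);
            }
            double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
            ux /= nrm; uy /= nrm; uz /= nrm;
          }
          if (outside) {
            if (axis == 2 && jz < 0) {
              tt.reflected += w;
              rc.rad_top.score(x, y, std::fabs(uz), w);
              rc.cart_top.score(x, y, ux, uy, uz, w);
              if (rc.fib_top.present)
                rc.fib_top.score(x, y, ux, uy, rc.n_above, w);
            } else if (axis == 2) {
              tt.transmitted += w;
              rc.rad_bot.score(x, y, std::fabs(uz), w);
              rc.cart_bot.score(x, y, ux, uy, uz, w);
            } else {
              tt.lateral += w;
            }
            break;
          }
          ix = jx; iy = jy; iz = jz;
          x += ux * nudge; y += uy * nudge; z += uz * nudge;
        }
      }
    }
  }
  return results_common(rc, tt);
}

// ----------------------------------------------------------------------
// Result packing
// ----------------------------------------------------------------------

static List results_common(RunCfg &rc, Totals &tt) {
  List out = List::create(
    _["n_packets"] = rc.n_packets,
    _["specular"] = tt.specular,
    _["reflected"] = tt.reflected,
    _["transmitted"] = tt.transmitted,
    _["absorbed"] = tt.absorbed,
    _["lateral"] = tt.lateral,
    _["layout_absorbed"] = tt.layout_absorbed,
    _["roulette_killed"] = tt.roulette_killed,
    _["roulette_boost"] = tt.roulette_boost,
    _["cutoff_killed"] = tt.cutoff_killed,
    _["launched_weight"] = tt.launched_weight,
    _["step_cap_hits"] = tt.step_cap_hits);
  if (rc.rad_top.present)
    out["radial_top"] = List::create(
      _["raw"] = wrap(rc.rad_top.raw), _["discarded"] = rc.rad_top.discarded,
      _["overflow"] = rc.rad_top.overflow);
  if (rc.rad_bot.present)
    out["radial_bottom"] = List::create(
      _["raw"] = wrap(rc.rad_bot.raw), _["discarded"] = rc.rad_bot.discarded,
      _["overflow"] = rc.rad_bot.overflow);
  if (rc.cart_top.present)
    out["cartesian_top"] = List::create(
      _["raw"] = wrap(rc.cart_top.raw), _["discarded"] = rc.cart_top.discarded,
      _["overflow"] = rc.cart_top.overflow);
  if (rc.cart_bot.present)
    out["cartesian_bottom"] = List::create(
      _["raw"] = wrap(rc.cart_bot.raw), _["discarded"] = rc.cart_bot.discarded,
      _["overflow"] = rc.cart_bot.overflow);
  if (rc.fib_top.present)
    out["fiber_top"] = List::create(
      _["raw"] = wrap(rc.fib_top.raw), _["discarded"] = rc.fib_top.discarded);
  if (rc.flu.present)
    out["fluence"] = List::create(
      _["raw"] = wrap(rc.flu.raw), _["offgrid"] = rc.flu.offgrid);
  if (rc.trace.present)
    out["trace"] = List::create(
      _["id"] = wrap(rc.trace.id), _["type"] = wrap(rc.trace.type),
      _["x"] = wrap(rc.trace.x), _["y"] = wrap(rc.trace.y),
      _["z"] = wrap(rc.trace.z),
      _["ux"] = wrap(rc.trace.ux), _["uy"] = wrap(rc.trace.uy),
      _["uz"] = wrap(rc.trace.uz), _["w"] = wrap(rc.trace.w),
      _["fate"] = wrap(rc.trace.fate), _["n_events"] = wrap(rc.trace.n_events),
      _["overflowed"] = wrap(rc.trace.overflowed),
      _["term_x"] = wrap(rc.trace.tx), _["term_y"] = wrap(rc.trace.ty),
      _["term_z"] = wrap(rc.trace.tz),
      _["term_ux"] = wrap(rc.trace.tux), _["term_uy"] = wrap(rc.trace.tuy),
      _["term_uz"] = wrap(rc.trace.tuz), _["term_w"] = wrap(rc.trace.tw));
  return out;
}

// ----------------------------------------------------------------------
// Sampling-volume voxelization: exact segment-voxel intersection lengths
// accumulated with each packet's terminal weight
// ----------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_compute_sv(IntegerVector id, NumericVector x, NumericVector y,
                    NumericVector z, LogicalVector keep,
                    NumericVector term_w, List grid) {
  double x0 = as<double>(grid["x0"]), dx = as<double>(grid["dx"]);
  double y0 = as<double>(grid["y0"]), dy = as<double>(grid["dy"]);
  double z0 = as<double>(grid["z0"]), dz = as<double>(grid["dz"]);
  int nx = as<int>(grid["nx"]), ny = as<int>(grid["ny"]),
      nz = as<int>(grid["nz"]);
  std::vector<double> sv((size_t)nx * ny * nz, 0.0);
  double total_in_grid = 0.0, total_out_grid = 0.0;
  double xmax = x0 + nx * dx, ymax = y0 + ny * dy, zmax = z0 + nz * dz;

  int nev = id.size();
  for (int i = 0; i + 1 < nev; ++i) {
    if (id[i] != id[i + 1]) continue;        // not consecutive events
    int pid = id[i];
    if (!keep[pid]) continue;
    double w = term_w[pid];
    double ax = x[i], ay = y[i], az = z[i];
    double bx = x[i + 1], by = y[i + 1], bz = z[i + 1];
    double vx = bx - ax, vy = by - ay, vz = bz - az;
    double L = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (L <= 0) continue;
    vx /= L; vy /= L; vz /= L;
    // clip the segment to the grid box ([t0, t1] along the segment)
    double t0 = 0.0, t1 = L;
    bool miss = false;
    const double lo[3] = {x0, y0, z0}, hi[3] = {xmax, ymax, zmax};
    const double p0[3] = {ax, ay, az}, v[3] = {vx, vy, vz};
    for (int a = 0; a < 3 && !miss; ++a) {
      if (v[a] == 0) {
        if (p0[a] < lo[a] || p0[a] >= hi[a]) miss = true;
      } else {
        double ta = (lo[a] - p0[a]) / v[a];
        double tb = (hi[a] - p0[a]) / v[a];
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
        if (t0 >= t1) miss = true;
      }
    }
    if (miss || t1 <= t0) { total_out_grid += L * w; continue; }
    total_out_grid += (L - (t1 - t0)) * w;
    // march across voxel faces from t0 to t1 (half-open convention)
    double t = t0;
    double eps = 1e-12 * std::max(1.0, L);
    while (t < t1 - eps) {
      double px = ax + vx * (t + eps), py = ay + vy * (t + eps),
             pz = az + vz * (t + eps);
      int ixv = (int)std::floor((px - x0) / dx);
      int iyv = (int)std::floor((py - y0) / dy);
      int izv = (int)std::floor((pz - z0) / dz);
      if (ixv < 0) ixv = 0; if (ixv >= nx) ixv = nx - 1;
      if (iyv < 0) iyv = 0; if (iyv >= ny) iyv = ny - 1;
      if (izv < 0) izv = 0; if (izv >= nz) izv = nz - 1;
      double txf = (vx > 0) ? ((x0 + (ixv + 1) * dx) - px) / vx
                 : (vx < 0) ? ((x0 + ixv * dx) - px) / vx : INF;
      double tyf = (vy > 0) ? ((y0 + (iyv + 1) * dy) - py) / vy
                 : (vy < 0) ? ((y0 + iyv * dy) - py) / vy : INF;
      double tzf = (vz > 0) ? ((z0 + (izv + 1) * dz) - pz) / vz
                 : (vz < 0) ? ((z0 + izv * dz) - pz) / vz : INF;
      double dnext = std::min(txf, std::min(tyf, tzf));
      if (dnext < 0) dnext = 0;
      double tend = std::min(t1, t + eps + dnext);
      double seg = tend - t;
      if (seg <= 0) seg = eps;
      sv[((size_t)izv * ny + iyv) * nx + ixv] += seg * w;
      total_in_grid += seg * w;
      t += seg;
    }
  }
  return List::create(_["sv"] = wrap(sv), _["in_grid"] = total_in_grid,
                      _["out_grid"] = total_out_grid);
}
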