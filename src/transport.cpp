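// Time-resolved white Monte Carlo photon transport in a semi-infinite
// homogeneous medium probed by two closely spaced optical fibers.
//
// The walk is simulated at zero absorption; absorption is applied later by
// Beer-Lambert reweighting of the stored per-record path lengths.  Detection
// supports two estimators:
//   * "crossing": a packet is detected when its transmitted exit position and
//     angle meet the fiber acceptance (the analog reference estimator);
//   * "escape": at every scattering vertex near the surface the expected
//     weight escaping straight into the detection cone and landing on the
//     detector is credited (last-scattering-vertex / next-event estimator).
// Both may use the azimuthal ring detector (annulus rho +/- det_radius,
// reweighted by the spot/annulus area ratio) or the literal detector spot.
//
// Variance reduction for the escape estimator:
//   * hot-zone splitting: the first time a lineage scatters near the
//     detector it is split n_split ways;
//   * one-step branching: at each vertex in the detection band the escape
//     credit of the *next* vertex is averaged over n_branch independent
//     virtual (scatter + flight) continuations, after which the real walk
//     adopts one of them unweighted (split with immediate Russian-roulette
//     recombination).  This averages out the strongly forward-peaked phase
//     function's alignment lottery, the dominant noise source;
//   * reachability pruning: packets that can no longer reach any detection
//     annulus within the remaining path budget are terminated as truncated.
//
// Similarity targets: with the anisotropy fixed, a walk at scattering
// coefficient mus evaluated against a detector annulus scaled by
// k = mus_target / mus is an exact realisation of the medium with
// mus_target and the unscaled detector -- free paths scale as 1/mus while
// every angular and Fresnel draw coincides.  `rho_scales` lists the k of
// each target; one walk ensemble then yields fully correlated records for
// every target (path lengths and depths are converted to target units at
// record time).  The only approximation is the unscaled source spot
// (25 um against a 1.25 mm separation).
//
// Random-number organisation: every launched photon owns a private walk
// stream (launch, free paths, phase function, boundary decisions of the
// backbone) and a private estimator stream (cone samples, branching);
// split copies derive their own pairs from (seed, photon, copy).  The walk
// stream feeds only scale-invariant draws, so same-seed runs at different
// mus follow spatially rescaled versions of the same trajectories.
//
// Geometry: the fiber-tip plane is z = 0 with the medium below, z growing
// with depth; the interface to the outside medium lies at
// z = -immersion_depth (0 for surface contact).  With immersion_depth > 0
// the detection plane (z = 0) lies inside the medium and detection needs no
// refraction; escape happens at the interface above.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3")
#endif

using namespace Rcpp;

namespace {

const double C_MM_PS = 0.299792458;  // speed of light, mm/ps

// xoshiro256++, seeded through splitmix64
struct Xoshiro {
  uint64_t s[4];
  Xoshiro() { s[0] = s[1] = s[2] = s[3] = 0x9e3779b97f4a7c15ULL; }
  static uint64_t splitmix(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) { reseed(seed); }
  void reseed(uint64_t seed) { for (int i = 0; i < 4; i++) s[i] = splitmix(seed); }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  inline double u01() { return (next() >> 11) * 0x1.0p-53; }        // [0, 1)
  inline double u01o() { return ((next() >> 11) + 1) * 0x1.0p-53; } // (0, 1]
};

// Henyey-Greenstein polar cosine by closed-form inverse CDF.
inline double hg_cos_one(double g, double u) {
  if (g == 0.0) return 2.0 * u - 1.0;
  double a = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - a * a) / (2.0 * g);
  return c > 1.0 ? 1.0 : (c < -1.0 ? -1.0 : c);
}

// uniform azimuth by Marsaglia rejection: cheaper than sin/cos of 2*pi*u,
// and the draw count depends only on the stream itself, preserving the
// scale-invariant correspondence of same-seed walks
inline void rand_azimuth(Xoshiro &r, double &c, double &s) {
  double v1, v2, ss;
  do {
    v1 = 2.0 * r.u01() - 1.0;
    v2 = 2.0 * r.u01() - 1.0;
    ss = v1 * v1 + v2 * v2;
  } while (ss > 1.0 || ss == 0.0);
  double inv = 1.0 / ss;
  c = (v1 * v1 - v2 * v2) * inv;
  s = 2.0 * v1 * v2 * inv;
}

// Unpolarized Fresnel reflectance, incidence from n1 into n2.
inline double fresnel_one(double n1, double n2, double ci) {
  if (ci < 0.0) ci = 0.0;
  if (ci > 1.0) ci = 1.0;
  double si = std::sqrt(1.0 - ci * ci);
  double st = si * n1 / n2;
  if (st >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(1.0 - st * st);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// geometric/time state of a packet between interactions
struct Geo {
  double x, y, z, ux, uy, uz, L, maxz;
  int m;
};

struct PhState {
  Geo geo;
  double w;
  bool split_done;
  bool at_vertex;  // popped copies re-do the vertex interaction first
  bool nee_sup;    // vertex escape credit already covered by a branch average
  bool far_a, far_b;  // beyond the distance-roulette radii (hysteresis)
  Xoshiro rw, rn;  // private walk and estimator streams
};

enum FlightOutcome { F_VERTEX, F_ESCAPED, F_TRUNCATED };

}  // namespace

//' @keywords internal
// [[Rcpp::export]]
NumericVector hg_cos_cpp(double g, NumericVector u) {
  int n = u.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = hg_cos_one(g, u[i]);
  return out;
}

//' @keywords internal
// [[Rcpp::export]]
NumericVector fresnel_unpolarized_cpp(double n1, double n2, NumericVector cos_incident) {
  int n = cos_incident.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = fresnel_one(n1, n2, cos_incident[i]);
  return out;
}

// [[Rcpp::export]]
List mc_white_run_cpp(double mus, double g, double n_in, double n_out,
                      double src_radius, double src_half_angle_deg,
                      double det_radius, double det_na,
                      double rho, double immersion_depth,
                      double bin_width_ps, double t_max_ps,
                      double n_launched_max, double n_detected_target,
                      double seed,
                      bool ring, bool escape_estimator,
                      int n_split, int k_cone, int n_branch,
                      double max_records, NumericVector rho_scales) {
  const int nbins = (int)std::lround(t_max_ps / bin_width_ps);
  const int n_t = rho_scales.size();                // similarity targets
  const double iz = -immersion_depth;               // interface plane
  const double Lmax = t_max_ps * C_MM_PS / n_in;    // path cutoff, target units
  const double cos_cone = std::cos(src_half_angle_deg * M_PI / 180.0);
  const double sin_c = det_na / n_in;               // in-medium detection cone
  const double cos_c = std::sqrt(1.0 - sin_c * sin_c);
  const double tan_c = sin_c / cos_c;
  const double omega_cone = 2.0 * M_PI * (1.0 - cos_c);
  const double ring_ratio = ring ? det_radius / (4.0 * rho) : 1.0;
  const double hg_norm = (1.0 - g * g) / (4.0 * M_PI);
  const double z_nee = 14.0 / mus;                  // exp(-14) tail cutoff
  const bool immersed = immersion_depth > 0.0;
  const bool fresnel_on_exit = !immersed;           // detection through interface?

  std::vector<double> kt(rho_scales.begin(), rho_scales.end());
  double k_max = 0.0;
  std::vector<double> ann_lo(n_t), ann_hi(n_t);     // annulus edges, run units
  for (int j = 0; j < n_t; j++) {
    ann_lo[j] = kt[j] * (rho - det_radius);
    ann_hi[j] = kt[j] * (rho + det_radius);
    if (kt[j] > k_max) k_max = kt[j];
  }
  const double r_lo = *std::min_element(ann_lo.begin(), ann_lo.end());
  const double r_hi = *std::max_element(ann_hi.begin(), ann_hi.end());
  const double Lmax_run = Lmax * k_max;             // longest walk needed
  const double zone_z = 0.5;                        // hot-zone split trigger, mm
  const double zone_r_lo = r_lo - 0.25, zone_r_hi = r_hi + 0.25;
  const double spot_margin = ring ? 0.0 : det_radius;
  const double branch_margin = 1.5 / mus;           // one mean free path

  const uint64_t base = (uint64_t)seed;
  std::vector<double> rw_, rL, rmaxz;
  std::vector<int> rm, rbin, rtgt;
  double w_det_phys = 0.0, w_esc = 0.0, w_trunc = 0.0, w_roul = 0.0;
  // two-level distance roulette (radius^2 / re-arm radius^2, mm^2)
  const double far2a = 2.5 * 2.5, near2a = 2.0 * 2.0;
  const double far2b = 5.0 * 5.0, near2b = 4.2 * 4.2;
  std::vector<double> sum_w(n_t, 0.0), sum_w2(n_t, 0.0);
  double launched = 0.0;
  long long n_steps = 0;
  std::vector<PhState> stack;
  std::vector<double> acc(n_t);
  Xoshiro rthin(base ^ 0xd2b74407b1ce6e93ULL);
  std::vector<double> floor_j(n_t, 0.0);
  const size_t buffer_cap = max_records > 0.0
    ? std::max((size_t)(2.5 * max_records * n_t), (size_t)1000000)
    : (size_t)-1;

  bool have_launch_budget = n_launched_max > 0.0;
  bool have_det_target = n_detected_target > 0.0;

  // unbiased record compression: roulette records below a per-target weight
  // floor (keep with probability w/F at weight F); repeated application at
  // growing floors composes to a single roulette at the final floor
  auto compress = [&](bool final_pass) {
    for (int j = 0; j < n_t; j++) {
      double F = sum_w[j] / max_records;
      if (!final_pass) F = std::max(F, 2.0 * floor_j[j]);
      floor_j[j] = std::max(floor_j[j], F);
    }
    size_t jj = 0;
    for (size_t i = 0; i < rw_.size(); i++) {
      double wi = rw_[i];
      double Fi = floor_j[rtgt[i]];
      if (wi < Fi) {
        if (rthin.u01() >= wi / Fi) continue;
        wi = Fi;
      }
      rw_[jj] = wi; rL[jj] = rL[i]; rm[jj] = rm[i];
      rmaxz[jj] = rmaxz[i]; rbin[jj] = rbin[i]; rtgt[jj] = rtgt[i];
      jj++;
    }
    rw_.resize(jj); rL.resize(jj); rm.resize(jj); rmaxz.resize(jj);
    rbin.resize(jj); rtgt.resize(jj);
  };

  double n_records_made = 0.0;
  auto record = [&](int tgt, double wc, double Lc, int mc, double mz) {
    double t = Lc * n_in / C_MM_PS;
    int b = (int)(t / bin_width_ps);
    if (b < 0 || b >= nbins) return;
    n_records_made += 1.0;
    sum_w[tgt] += wc; sum_w2[tgt] += wc * wc;
    double Fi = floor_j[tgt];
    if (wc < Fi) {  // roulette straight at the current floor
      if (rthin.u01() >= wc / Fi) return;
      wc = Fi;
    }
    rw_.push_back(wc); rL.push_back(Lc); rm.push_back(mc);
    rmaxz.push_back(mz); rbin.push_back(b); rtgt.push_back(tgt);
    if (rw_.size() > buffer_cap) compress(false);
  };

  // within the radial/depth band where the escape estimator can fire?
  auto in_nee_band = [&](const Geo &p, double margin) {
    if (p.z <= 0.0 || p.z >= z_nee + margin) return false;
    double rr = std::sqrt(p.x * p.x + p.y * p.y);
    double reach = p.z * tan_c + spot_margin + margin;
    return rr > r_lo - reach && rr < r_hi + reach;
  };

  // Expected escape into the detection cone from a vertex, k_cone samples;
  // one record per matching similarity target.
  auto nee_credit = [&](Xoshiro &rn, const Geo &p, double w) {
    std::fill(acc.begin(), acc.end(), 0.0);
    bool any = false;
    for (int k = 0; k < k_cone; k++) {
      double ce = 1.0 - rn.u01() * (1.0 - cos_c);       // cos from upward axis
      double se = std::sqrt(1.0 - ce * ce);
      double cpe, spe;
      rand_azimuth(rn, cpe, spe);
      double d = p.z / ce;
      double lx = p.x + se * cpe * d, ly = p.y + se * spe * d;
      double rl2 = lx * lx + ly * ly;
      double q = 0.0;  // angular/attenuation factor, target-independent
      for (int j = 0; j < n_t; j++) {
        bool hit;
        if (ring) hit = (rl2 >= ann_lo[j] * ann_lo[j] && rl2 <= ann_hi[j] * ann_hi[j]);
        else {
          double dx = lx - kt[j] * rho, rr = kt[j] * det_radius;
          hit = (dx * dx + ly * ly <= rr * rr);
        }
        if (!hit) continue;
        if (q == 0.0) {
          double T = fresnel_on_exit ? 1.0 - fresnel_one(n_in, n_out, ce) : 1.0;
          if (T <= 0.0) { q = -1.0; break; }
          double mu = p.ux * se * cpe + p.uy * se * spe - p.uz * ce;
          double den = 1.0 + g * g - 2.0 * g * mu;
          q = hg_norm / (den * std::sqrt(den)) * T * std::exp(-mus * d);
        }
        acc[j] += q;
        any = true;
      }
    }
    if (!any) return;
    double d_mid = p.z / (0.5 * (1.0 + cos_c));
    for (int j = 0; j < n_t; j++) {
      if (acc[j] <= 0.0) continue;
      double wc = w * acc[j] * omega_cone * ring_ratio / k_cone;
      record(j, wc, (p.L + d_mid) / kt[j], p.m, p.maxz / kt[j]);
    }
  };

  // apply a Henyey-Greenstein scattering to the direction in p
  auto scatter = [&](Geo &p, Xoshiro &r) {
    double ct = hg_cos_one(g, r.u01());
    double st = std::sqrt(1.0 - ct * ct);
    double cp, sp;
    rand_azimuth(r, cp, sp);
    if (std::fabs(p.uz) > 0.99999) {
      p.ux = st * cp; p.uy = st * sp; p.uz = ct * (p.uz > 0 ? 1.0 : -1.0);
    } else {
      double den = std::sqrt(1.0 - p.uz * p.uz);
      double nux = st * (p.ux * p.uz * cp - p.uy * sp) / den + p.ux * ct;
      double nuy = st * (p.uy * p.uz * cp + p.ux * sp) / den + p.uy * ct;
      double nuz = -st * cp * den + p.uz * ct;
      p.ux = nux; p.uy = nuy; p.uz = nuz;
    }
  };

  // one free flight from a vertex-ready state (direction already set):
  // handles interface reflections, escape-mode only.  Advances p to the
  // next scattering vertex or reports escape/truncation; no tallies.
  auto flight_escape = [&](Geo &p, Xoshiro &r) -> FlightOutcome {
    double s = -std::log(r.u01o()) / mus;
    while (p.uz < 0.0 && p.z + p.uz * s < iz) {
      double s1 = (iz - p.z) / p.uz;
      if (p.L + s1 >= Lmax_run) return F_TRUNCATED;
      p.x += p.ux * s1; p.y += p.uy * s1; p.z = iz; p.L += s1; s -= s1;
      double R = fresnel_one(n_in, n_out, -p.uz);
      if (r.u01() < R) p.uz = -p.uz;
      else return F_ESCAPED;
    }
    if (p.L + s >= Lmax_run) return F_TRUNCATED;
    p.x += p.ux * s; p.y += p.uy * s; p.z += p.uz * s; p.L += s;
    if (p.z > p.maxz) p.maxz = p.z;
    p.m++;
    n_steps++;
    return F_VERTEX;
  };

  // can the packet still reach a detection annulus within its budget?
  auto reachable = [&](const Geo &p) {
    double rr = std::sqrt(p.x * p.x + p.y * p.y);
    double drad = rr > r_hi ? rr - r_hi : (rr < r_lo ? r_lo - rr : 0.0);
    double rem = Lmax_run - p.L;
    return p.z * p.z + drad * drad <= rem * rem;
  };

  auto maybe_split = [&](PhState &ps, uint64_t iph, bool nee_suppressed) {
    if (ps.split_done || n_split <= 1) return;
    const Geo &p = ps.geo;
    if (p.z <= 0.0 || p.z >= zone_z) return;
    double rr = std::sqrt(p.x * p.x + p.y * p.y);
    if (rr <= zone_r_lo || rr >= zone_r_hi) return;
    ps.split_done = true;
    ps.w /= n_split;
    for (int c = 1; c < n_split; c++) {
      PhState q = ps;
      q.at_vertex = true;
      q.nee_sup = nee_suppressed;
      uint64_t cs = base + 0x632be59bd9b4e019ULL * iph +
        0x94d049bb133111ebULL * (uint64_t)c;
      q.rw.reseed(cs);
      q.rn.reseed(cs + 0x9e3779b97f4a7c15ULL);
      stack.push_back(q);
    }
  };

  while (true) {
    if (have_det_target && (double)rw_.size() >= n_detected_target) break;
    if (have_launch_budget && launched >= n_launched_max) break;
    if (!have_det_target && !have_launch_budget) break;  // guarded in R
    launched += 1.0;
    uint64_t iph = (uint64_t)launched;
    if (iph % 16384 == 0) Rcpp::checkUserInterrupt();

    PhState p0;
    p0.rw.reseed(base + 0x632be59bd9b4e019ULL * iph);
    p0.rn.reseed(base + 0x632be59bd9b4e019ULL * iph + 0x9e3779b97f4a7c15ULL);
    double r0 = src_radius * std::sqrt(p0.rw.u01());
    double c0, s0l;
    rand_azimuth(p0.rw, c0, s0l);
    double cz = 1.0 - p0.rw.u01() * (1.0 - cos_cone);
    double sz = std::sqrt(1.0 - cz * cz);
    double c1, s1l;
    rand_azimuth(p0.rw, c1, s1l);
    p0.geo = Geo{r0 * c0, r0 * s0l, 0.0, sz * c1, sz * s1l, cz, 0.0, 0.0, 0};
    p0.w = 1.0;
    p0.split_done = false; p0.at_vertex = false; p0.nee_sup = false;
    p0.far_a = false; p0.far_b = false;
    stack.clear();
    stack.push_back(p0);

    while (!stack.empty()) {
      PhState ps = stack.back();
      stack.pop_back();

      if (!escape_estimator) {
        // ---- analog crossing estimator (reference path) ----
        Geo &p = ps.geo;
        Xoshiro &rw = ps.rw;
        if (ps.at_vertex) scatter(p, rw);  // split copy resumes at its vertex
        bool alive = true;
        while (alive) {
          double s = -std::log(rw.u01o()) / mus;
          // detection-plane crossing inside the medium (immersed probes;
          // single-target runs, enforced by the R wrapper)
          if (immersed && p.z > 0.0 && p.uz < 0.0 && p.z + p.uz * s < 0.0) {
            double sp = -p.z / p.uz;
            if (p.L + sp < Lmax_run) {
              double cx = p.x + p.ux * sp, cy = p.y + p.uy * sp;
              double st_med = std::sqrt(1.0 - p.uz * p.uz);
              bool hit;
              if (ring) {
                double rr2 = cx * cx + cy * cy;
                hit = (rr2 >= ann_lo[0] * ann_lo[0] && rr2 <= ann_hi[0] * ann_hi[0]);
              } else {
                double dx = cx - kt[0] * rho, rr = kt[0] * det_radius;
                hit = (dx * dx + cy * cy <= rr * rr);
              }
              if (hit && st_med <= sin_c) {
                record(0, ps.w * ring_ratio, (p.L + sp) / kt[0], p.m, p.maxz / kt[0]);
                w_det_phys += ps.w;
                break;  // packet enters the fiber
              }
            }
          }
          bool terminated = false;
          while (p.uz < 0.0 && p.z + p.uz * s < iz) {
            double s1 = (iz - p.z) / p.uz;
            if (p.L + s1 >= Lmax_run) { w_trunc += ps.w; terminated = true; break; }
            p.x += p.ux * s1; p.y += p.uy * s1; p.z = iz; p.L += s1; s -= s1;
            double ci = -p.uz;
            double R = fresnel_one(n_in, n_out, ci);
            if (rw.u01() < R) {
              p.uz = -p.uz;
            } else {
              if (!immersed) {
                double st_out = std::sqrt(1.0 - ci * ci) * n_in / n_out;
                bool detected = false;
                if (st_out <= det_na) {
                  double rr2 = p.x * p.x + p.y * p.y;
                  for (int j = 0; j < n_t; j++) {
                    bool hit;
                    if (ring) hit = (rr2 >= ann_lo[j] * ann_lo[j] &&
                                     rr2 <= ann_hi[j] * ann_hi[j]);
                    else {
                      double dx = p.x - kt[j] * rho, rr = kt[j] * det_radius;
                      hit = (dx * dx + p.y * p.y <= rr * rr);
                    }
                    if (hit) {
                      record(j, ps.w * ring_ratio, p.L / kt[j], p.m, p.maxz / kt[j]);
                      detected = true;
                    }
                  }
                }
                if (detected) w_det_phys += ps.w; else w_esc += ps.w;
              } else w_esc += ps.w;
              terminated = true;
              break;
            }
          }
          if (terminated) break;
          if (p.L + s >= Lmax_run) { w_trunc += ps.w; break; }
          p.x += p.ux * s; p.y += p.uy * s; p.z += p.uz * s; p.L += s;
          if (p.z > p.maxz) p.maxz = p.z;
          p.m++;
          n_steps++;
          if (!reachable(p)) { w_trunc += ps.w; break; }
          maybe_split(ps, iph, false);
          scatter(p, rw);
        }
        continue;
      }

      // ---- escape estimator ----
      bool alive = true;
      bool nee_suppressed = ps.at_vertex && ps.nee_sup;
      if (!ps.at_vertex) {
        // initial flight from the launch point (direction preset)
        switch (flight_escape(ps.geo, ps.rw)) {
        case F_ESCAPED: w_esc += ps.w; alive = false; break;
        case F_TRUNCATED: w_trunc += ps.w; alive = false; break;
        case F_VERTEX: break;
        }
      }
      while (alive) {
        // vertex processing
        if (!reachable(ps.geo)) { w_trunc += ps.w; break; }
        // distance roulette: packets far from the detection region are
        // killed with probability 1/2 and the survivors doubled (unbiased;
        // expectation-neutral weight flow tracked in w_roul)
        {
          const Geo &p = ps.geo;
          double rr = std::sqrt(p.x * p.x + p.y * p.y);
          double drad = rr > r_hi ? rr - r_hi : (rr < r_lo ? r_lo - rr : 0.0);
          double d2 = p.z * p.z + drad * drad;
          bool killed = false;
          if (!ps.far_a && d2 > far2a) {
            ps.far_a = true;
            if (ps.rw.u01() < 0.5) { w_roul += ps.w; killed = true; }
            else { w_roul -= ps.w; ps.w *= 2.0; }
          } else if (ps.far_a && d2 < near2a) ps.far_a = false;
          if (!killed) {
            if (!ps.far_b && d2 > far2b) {
              ps.far_b = true;
              if (ps.rw.u01() < 0.5) { w_roul += ps.w; killed = true; }
              else { w_roul -= ps.w; ps.w *= 2.0; }
            } else if (ps.far_b && d2 < near2b) ps.far_b = false;
          }
          if (killed) break;
        }
        maybe_split(ps, iph, nee_suppressed);
        if (!nee_suppressed && in_nee_band(ps.geo, 0.0))
          nee_credit(ps.rn, ps.geo, ps.w);
        nee_suppressed = false;
        // one-step branching with recombination: average the next vertex's
        // escape credit over n_branch virtual continuations, then adopt one
        if (n_branch > 1 && in_nee_band(ps.geo, branch_margin)) {
          int pick = (int)(ps.rn.u01() * n_branch);
          if (pick >= n_branch) pick = n_branch - 1;
          Geo adopted{};
          FlightOutcome adopted_out = F_VERTEX;
          double wb = ps.w / n_branch;
          for (int b = 0; b < n_branch; b++) {
            Geo q = ps.geo;
            scatter(q, ps.rn);
            FlightOutcome out = flight_escape(q, ps.rn);
            if (out == F_VERTEX && in_nee_band(q, 0.0))
              nee_credit(ps.rn, q, wb);
            if (b == pick) { adopted = q; adopted_out = out; }
          }
          if (adopted_out == F_ESCAPED) { w_esc += ps.w; break; }
          if (adopted_out == F_TRUNCATED) { w_trunc += ps.w; break; }
          ps.geo = adopted;
          nee_suppressed = true;   // its escape credit was just averaged
          continue;                // resume processing at the adopted vertex
        }
        // ordinary continuation
        scatter(ps.geo, ps.rw);
        switch (flight_escape(ps.geo, ps.rw)) {
        case F_ESCAPED: w_esc += ps.w; alive = false; break;
        case F_TRUNCATED: w_trunc += ps.w; alive = false; break;
        case F_VERTEX: break;
        }
      }
    }
  }

  NumericVector ess(n_t);
  for (int j = 0; j < n_t; j++)
    ess[j] = sum_w2[j] > 0.0 ? sum_w[j] * sum_w[j] / sum_w2[j] : 0.0;
  double n_records_raw = n_records_made;
  if (max_records > 0.0 && (double)rw_.size() > max_records * n_t)
    compress(true);

  double sum_w_all = 0.0;
  for (int j = 0; j < n_t; j++) sum_w_all += sum_w[j];
  double det_weight = escape_estimator ? sum_w_all : w_det_phys;
  return List::create(
    _["weight"] = NumericVector(rw_.begin(), rw_.end()),
    _["path_length"] = NumericVector(rL.begin(), rL.end()),
    _["n_scatter"] = IntegerVector(rm.begin(), rm.end()),
    _["max_depth"] = NumericVector(rmaxz.begin(), rmaxz.end()),
    _["arrival_bin"] = IntegerVector(rbin.begin(), rbin.end()),
    _["target"] = IntegerVector(rtgt.begin(), rtgt.end()),
    _["n_launched"] = launched,
    _["launched_weight"] = launched,
    _["detected_weight"] = det_weight,
    _["escaped_weight"] = w_esc,
    _["truncated_weight"] = w_trunc,
    _["rouletted_weight"] = w_roul,
    _["n_records_raw"] = n_records_raw,
    _["ess"] = ess,
    _["n_steps"] = (double)n_steps);
}
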