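#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Full linear (open) discrete convolution, O(n*m).
// Direct summation keeps small elements accurate to relative machine
// precision, which FFT convolution does not guarantee for bins whose
// value is many orders of magnitude below the curve maximum.
// [[Rcpp::export]]
NumericVector conv_direct(NumericVector x, NumericVector y) {
  const int nx = x.size(), ny = y.size();
  if (nx == 0 || ny == 0) stop("conv_direct: empty input");
  NumericVector out(nx + ny - 1);
  for (int i = 0; i < nx; ++i) {
    const double xi = x[i];
    if (xi == 0.0) continue;
    for (int j = 0; j < ny; ++j) out[i + j] += xi * y[j];
  }
  return out;
}

// --- self-contained RNG (splitmix64 seeding a xoshiro256+) so the MC
//     oracle is reproducible from an integer seed independent of R's RNG;
//     each photon gets its own substream so paths can be replayed ---
namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]; never 0 so -log(u) is finite
  double runif() {
    return (static_cast<double>(next() >> 11) + 1.0) * (1.0 / 9007199254740993.0);
  }
};

// chord length of segment p0 -> p0 + s*dir (0 <= s <= slen) inside a sphere
double sphere_chord(const double p0[3], const double dir[3], double slen,
                    const double c[3], double r) {
  double oc[3] = {p0[0] - c[0], p0[1] - c[1], p0[2] - c[2]};
  double b = oc[0] * dir[0] + oc[1] * dir[1] + oc[2] * dir[2];
  double cc = oc[0] * oc[0] + oc[1] * oc[1] + oc[2] * oc[2] - r * r;
  double disc = b * b - cc;
  if (disc <= 0.0) return 0.0;
  double sq = std::sqrt(disc);
  double t0 = -b - sq, t1 = -b + sq;
  if (t0 < 0.0) t0 = 0.0;
  if (t1 > slen) t1 = slen;
  return (t1 > t0) ? (t1 - t0) : 0.0;
}

// unpolarized Fresnel reflectance for internal incidence cosine ci,
// refractive indices n_in -> n_out
double fresnel_R(double ci, double n_in, double n_out) {
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = n_in / n_out * si;
  if (st >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(1.0 - st * st);
  double rs = (n_in * ci - n_out * ct) / (n_in * ci + n_out * ct);
  double rp = (n_in * ct - n_out * ci) / (n_in * ct + n_out * ci);
  return 0.5 * (rs * rs + rp * rp);
}

struct FlightResult {
  int outcome;        // 0 absorbed-out (expired), 1 escaped, -1 none
  double w;           // weight at exit
  double L;           // total pathlength at exit, cm
  double lpert;       // partial pathlength inside the tracked sphere, cm
  double x, y;        // exit position
  double absorbed;    // weight deposited by absorption
  double expired;     // weight killed at the time cap
};

// propagate one photon packet; if track, accumulate the chord length
// inside the sphere at center pc with radius pr. The RNG stream fully
// determines the path, so a second call with the same stream replays it.
FlightResult propagate(Xoshiro &rng, double mua, double musp,
                       double n_in, double n_out, double L_max,
                       bool track, const double pc[3], double pr) {
  FlightResult res;
  res.outcome = -1; res.lpert = 0.0; res.absorbed = 0.0; res.expired = 0.0;
  double p[3] = {0.0, 0.0, 0.0};
  double u[3] = {0.0, 0.0, 1.0};
  double w = 1.0, L = 0.0;
  for (;;) {
    double s = -std::log(rng.runif()) / musp;
    while (s > 0.0) {
      double s_seg = s;
      bool hits_boundary = false;
      if (u[2] < 0.0) {
        double s_b = -p[2] / u[2];
        if (s_b <= s_seg) { s_seg = s_b; hits_boundary = true; }
      }
      if (L + s_seg > L_max) {  // time cap
        double s_cap = L_max - L;
        double wa = w * (1.0 - std::exp(-mua * s_cap));
        res.absorbed += wa;
        res.expired = w - wa;
        res.outcome = 0; res.w = 0.0; res.L = L_max;
        res.x = p[0]; res.y = p[1];
        return res;
      }
      if (track) res.lpert += sphere_chord(p, u, s_seg, pc, pr);
      double w_new = w * std::exp(-mua * s_seg);
      res.absorbed += w - w_new;
      w = w_new;
      p[0] += s_seg * u[0]; p[1] += s_seg * u[1]; p[2] += s_seg * u[2];
      L += s_seg;
      s -= s_seg;
      if (hits_boundary) {
        p[2] = 0.0;
        double ci = -u[2];
        if (rng.runif() < fresnel_R(ci, n_in, n_out)) {
          u[2] = -u[2];  // internal reflection, finish the step inside
        } else {
          res.outcome = 1; res.w = w; res.L = L;
          res.x = p[0]; res.y = p[1];
          return res;
        }
      }
    }
    double cz = 2.0 * rng.runif() - 1.0;
    double sz = std::sqrt(std::max(0.0, 1.0 - cz * cz));
    double phi = 2.0 * M_PI * rng.runif();
    u[0] = sz * std::cos(phi); u[1] = sz * std::sin(phi); u[2] = cz;
  }
}

}  // namespace

// Photon-packet Monte Carlo in a semi-infinite half-space z > 0.
// Isotropic scattering at rate musp (g = 0), continuous absorption
// weighting, Fresnel internal reflection at the z = 0 boundary.
// Detection: photons escaping in an annulus |r - rho| <= det_halfwidth.
// The detector of the analytical model is the point (rho, 0, 0); by the
// axial symmetry of the source, a photon detected at azimuth phi is
// statistically a point-detector photon whose path is rotated by phi, so
// its partial pathlength through the perturbation sphere is evaluated for
// the sphere center rotated by phi about the z axis (a replay pass over
// the photon's private RNG substream). Perturbed detection weights are
// w * exp(-delta_mua * l_pert).
// [[Rcpp::export]]
List mc_semiinf(double mua, double musp, double n_in, double n_out,
                double rho, double det_halfwidth,
                NumericVector pert_center, double pert_radius,
                double delta_mua, int n_photons, double seed,
                double v_cm_ps, double t_max_ps,
                double bin_width_ps, int n_bins) {
  if (musp <= 0 || mua < 0) stop("mc_semiinf: invalid optical properties");
  if (n_photons < 1) stop("mc_semiinf: n_photons must be positive");
  const uint64_t base = static_cast<uint64_t>(seed);
  const double pc0[3] = {pert_center[0], pert_center[1], pert_center[2]};
  const double L_max = t_max_ps * v_cm_ps;

  std::vector<double> det_w, det_wp, det_t;
  NumericVector hist0(n_bins), hist_pert(n_bins);
  double absorbed = 0.0, escaped_other = 0.0, expired = 0.0, detected = 0.0;
  const double none[3] = {0.0, 0.0, 0.0};

  for (int ip = 0; ip < n_photons; ++ip) {
    const uint64_t stream = base * 0x100000000ULL + static_cast<uint64_t>(ip);
    Xoshiro rng(stream);
    FlightResult fr = propagate(rng, mua, musp, n_in, n_out, L_max,
                                false, none, 0.0);
    if (fr.outcome == 1) {
      double r = std::sqrt(fr.x * fr.x + fr.y * fr.y);
      if (std::fabs(r - rho) <= det_halfwidth) {
        // replay with the perturbation rotated to the exit azimuth
        double lpert = 0.0;
        if (delta_mua != 0.0 && pert_radius > 0.0 && r > 0.0) {
          double cphi = fr.x / r, sphi = fr.y / r;
          double pc[3] = {cphi * pc0[0] - sphi * pc0[1],
                          sphi * pc0[0] + cphi * pc0[1], pc0[2]};
          Xoshiro rng2(stream);
          FlightResult fr2 = propagate(rng2, mua, musp, n_in, n_out,
                                       L_max, true, pc, pert_radius);
          lpert = fr2.lpert;
        }
        double t_ps = fr.L / v_cm_ps;
        double wp = fr.w * std::exp(-delta_mua * lpert);
        detected += fr.w;
        det_w.push_back(fr.w);
        det_wp.push_back(wp);
        det_t.push_back(t_ps);
        int ib = static_cast<int>(t_ps / bin_width_ps);
        if (ib >= 0 && ib < n_bins) {
          hist0[ib] += fr.w;
          hist_pert[ib] += wp;
        }
      } else {
        escaped_other += fr.w;
      }
    }
    absorbed += fr.absorbed;
    expired += fr.expired;
  }

  return List::create(
    _["w"] = wrap(det_w), _["w_pert"] = wrap(det_wp), _["t_ps"] = wrap(det_t),
    _["hist"] = hist0, _["hist_pert"] = hist_pert,
    _["detected"] = detected, _["escaped_other"] = escaped_other,
    _["absorbed"] = absorbed, _["expired"] = expired,
    _["launched"] = static_cast<double>(n_photons));
}
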