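// Hot loops for the pulse-echo simulator and delay-and-sum beamformer.
// Conventions: SI units throughout; positions are n x 3 matrices with
// columns (x lateral, y elevational, z axial into tissue); delays are per
// element, normalized to min 0 within an event.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sinc_pi(double u) {
  if (std::fabs(u) < 1e-12) return 1.0;
  double pu = M_PI * u;
  return std::sin(pu) / pu;
}

// Gaussian-modulated cosine pulse, unit peak envelope.
static inline double gauss_pulse(double tau, double fc, double sigma_t) {
  return std::exp(-0.5 * tau * tau / (sigma_t * sigma_t)) *
         std::cos(2.0 * M_PI * fc * tau);
}

// Dense lookup table of the pulse over [-support, support] for the inner
// accumulation loops (linear interpolation; ~1000 points per carrier
// period keeps the interpolation error ~1e-5 of peak).
struct PulseTable {
  std::vector<double> v;
  double support, step;
  PulseTable(double fc, double sigma_t) {
    support = 4.0 * sigma_t;
    const int n = (int)std::ceil(2.0 * support * fc * 1000.0) + 2;
    step = 2.0 * support / (n - 1);
    v.resize(n);
    for (int i = 0; i < n; ++i)
      v[i] = gauss_pulse(-support + i * step, fc, sigma_t);
  }
  inline double operator()(double tau) const {
    const double f = (tau + support) / step;
    if (f < 0.0 || f >= (double)(v.size() - 1)) return 0.0;
    const int i = (int)f;
    const double w = f - i;
    return (1.0 - w) * v[i] + w * v[i + 1];
  }
};

// Far-field rectangular-aperture directivity times soft-baffle obliquity.
// ux: direction cosine along the element's lateral axis, uy elevational,
// un along the element normal (clamped at 0 behind the baffle).
static inline double directivity(double ux, double uy, double un,
                                 double width, double length, double lambda) {
  if (un <= 0.0) return 0.0;
  return sinc_pi(width * ux / lambda) * sinc_pi(length * uy / lambda) * un;
}

// Per-element local frame from the normal (normal assumed in the x-z
// plane for this device): lateral axis = normal rotated -90 deg about y,
// elevational axis = +y.
static inline void elem_frame(double nx, double nz, double* lx, double* lz) {
  *lx = nz;
  *lz = -nx;
}

// [[Rcpp::export]]
NumericMatrix cpp_channel_event(NumericMatrix elem, NumericMatrix normals,
                                NumericVector delays, NumericVector apod,
                                NumericMatrix scat, NumericVector amps,
                                double fc, double sigma_t, double c,
                                double fs, double t0, int n_samples,
                                double width, double length) {
  const int E = elem.nrow(), N = scat.nrow();
  const double lambda = c / fc;
  const double support = 4.0 * sigma_t;
  const PulseTable pt(fc, sigma_t);
  NumericMatrix out(n_samples, E);

  std::vector<double> dist(E), dirw(E);
  for (int s = 0; s < N; ++s) {
    const double px = scat(s, 0), py = scat(s, 1), pz = scat(s, 2);
    // transmit wavefront first arrival at the scatterer
    double t_tx = R_PosInf;
    int e_tx = 0;
    for (int e = 0; e < E; ++e) {
      const double dx = px - elem(e, 0), dy = py - elem(e, 1),
                   dz = pz - elem(e, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      dist[e] = d;
      const double t = delays[e] + d / c;
      if (t < t_tx) { t_tx = t; e_tx = e; }
      double lx, lz;
      elem_frame(normals(e, 0), normals(e, 2), &lx, &lz);
      const double ux = (dx * lx + dz * lz) / d;
      const double uy = dy / d;
      const double un = (dx * normals(e, 0) + dy * normals(e, 1) +
                         dz * normals(e, 2)) / d;
      dirw[e] = directivity(ux, uy, un, width, length, lambda);
    }
    const double a_tx =
        amps[s] * apod[e_tx] * dirw[e_tx] / std::max(dist[e_tx], 1e-6);
    if (a_tx == 0.0) continue;
    for (int e = 0; e < E; ++e) {
      const double a = a_tx * dirw[e] / std::max(dist[e], 1e-6);
      if (a == 0.0) continue;
      const double t_arr = t_tx + dist[e] / c;
      int i0 = (int)std::ceil((t_arr - support - t0) * fs);
      int i1 = (int)std::floor((t_arr + support - t0) * fs);
      if (i0 < 0) i0 = 0;
      if (i1 > n_samples - 1) i1 = n_samples - 1;
      double* col = &out(0, e);
      for (int i = i0; i <= i1; ++i) {
        const double tau = t0 + i / fs - t_arr;
        col[i] += a * pt(tau);
      }
    }
  }
  return out;
}

// Delay-and-sum one event of analytic channel data onto arbitrary pixels.
// re/im: samples (time x element). Returns re, im and contributing-element
// count per pixel (coverage).
// [[Rcpp::export]]
List cpp_das_event(NumericMatrix re, NumericMatrix im, NumericMatrix elem,
                   NumericVector delays, NumericVector px, NumericVector pz,
                   double c, double fs, double t0, double f_number,
                   NumericVector rx_apod) {
  const int T = re.nrow(), E = elem.nrow();
  const int P = px.size();
  NumericVector ore(P), oim(P);
  IntegerVector cov(P);

  for (int p = 0; p < P; ++p) {
    const double x = px[p], z = pz[p];
    // transmit arrival: first wavefront arrival consistent with the law
    double t_tx = R_PosInf;
    for (int e = 0; e < E; ++e) {
      const double dx = x - elem(e, 0), dz = z - elem(e, 2),
                   dy = elem(e, 1);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double t = delays[e] + d / c;
      if (t < t_tx) t_tx = t;
    }
    // receive aperture policy: f_number > 0 selects an angle-based
    // dynamic aperture (acceptance |tan(theta)| <= 1 / (2 f#), Hann
    // tapered, falling back to the full aperture for sector pixels
    // outside every element's cone); f_number <= 0 uses the full
    // aperture with the fixed rx_apod weights (phased-array mode)
    const double tan_max = (f_number > 0) ? 1.0 / (2.0 * f_number)
                                          : R_PosInf;
    std::vector<double> wsum(E);
    int n_in = 0;
    for (int e = 0; e < E; ++e) {
      if (f_number <= 0) {
        wsum[e] = rx_apod[e];
        ++n_in;
        continue;
      }
      const double dx = x - elem(e, 0), dz = z - elem(e, 2);
      const double t = (dz > 0) ? std::fabs(dx) / dz : R_PosInf;
      if (t <= tan_max) {
        wsum[e] = 0.5 + 0.5 * std::cos(M_PI * t / tan_max);
        ++n_in;
      } else {
        wsum[e] = 0.0;
      }
    }
    double sr = 0.0, si = 0.0;
    int n_used = 0;
    for (int e = 0; e < E; ++e) {
      const double w = (n_in > 0) ? wsum[e] : 1.0;
      if (w == 0.0) continue;
      const double dx = x - elem(e, 0), dz = z - elem(e, 2),
                   dy = elem(e, 1);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double tau = t_tx + d / c;
      const double fi = (tau - t0) * fs;
      const int i0 = (int)std::floor(fi);
      if (i0 < 0 || i0 >= T - 1) continue;
      const double w_t = fi - i0;
      sr += w * ((1.0 - w_t) * re(i0, e) + w_t * re(i0 + 1, e));
      si += w * ((1.0 - w_t) * im(i0, e) + w_t * im(i0 + 1, e));
      ++n_used;
    }
    ore[p] = sr;
    oim[p] = si;
    cov[p] = n_used;
  }
  return List::create(_["re"] = ore, _["im"] = oim, _["coverage"] = cov);
}

// Delay-and-sum and coherently compound all events in one pass.
// re/im: (time x element*event), delays: (element x event).
// [[Rcpp::export]]
List cpp_das_compound(NumericMatrix re, NumericMatrix im,
                      NumericMatrix elem, NumericMatrix delays,
                      NumericVector weights, NumericVector px,
                      NumericVector pz, double c, double fs, double t0,
                      double f_number, NumericVector rx_apod) {
  const int T = re.nrow(), E = elem.nrow(), K = delays.ncol();
  const int P = px.size();
  NumericVector ore(P), oim(P);
  IntegerVector cov(P);
  // precompute element x and pixel-independent pointers
  for (int p = 0; p < P; ++p) {
    const double x = px[p], z = pz[p];
    const double tan_max = (f_number > 0) ? 1.0 / (2.0 * f_number)
                                          : R_PosInf;
    double sr = 0.0, si = 0.0;
    int n_used = 0, n_in = 0;
    std::vector<double> d(E), w(E);
    for (int e = 0; e < E; ++e) {
      const double dx = x - elem(e, 0), dz = z - elem(e, 2),
                   dy = elem(e, 1);
      d[e] = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (f_number <= 0) {
        w[e] = rx_apod[e];
        ++n_in;
        continue;
      }
      const double t = (dz > 0) ? std::fabs(dx) / dz : R_PosInf;
      if (t <= tan_max) {
        w[e] = 0.5 + 0.5 * std::cos(M_PI * t / tan_max);
        ++n_in;
      } else {
        w[e] = 0.0;
      }
    }
    if (n_in == 0) std::fill(w.begin(), w.end(), 1.0);
    for (int k = 0; k < K; ++k) {
      double t_tx = R_PosInf;
      for (int e = 0; e < E; ++e) {
        const double t = delays(e, k) + d[e] / c;
        if (t < t_tx) t_tx = t;
      }
      const int off = k * E;
      for (int e = 0; e < E; ++e) {
        if (w[e] == 0.0) continue;
        const double fi = (t_tx + d[e] / c - t0) * fs;
        const int i0 = (int)fi;
        if (fi < 0.0 || i0 >= T - 1) continue;
        const double wt = fi - i0;
        const double ww = weights[k] * w[e];
        sr += ww * ((1.0 - wt) * re(i0, off + e) + wt * re(i0 + 1, off + e));
        si += ww * ((1.0 - wt) * im(i0, off + e) + wt * im(i0 + 1, off + e));
        ++n_used;
      }
    }
    ore[p] = sr;
    oim[p] = si;
    cov[p] = n_used;
  }
  return List::create(_["re"] = ore, _["im"] = oim, _["coverage"] = cov);
}

// Transmitted-pressure field of one event: per point, the sum over the
// common time record of the squared superposed element pulses (the caller
// divides by n and takes the square root).
// [[Rcpp::export]]
NumericVector cpp_field_event(NumericMatrix elem, NumericMatrix normals,
                              NumericVector delays, NumericVector apod,
                              NumericVector px, NumericVector py,
                              NumericVector pz, double fc, double sigma_t,
                              double c, double fs, double width,
                              double length) {
  const int E = elem.nrow(), P = px.size();
  const double lambda = c / fc;
  const double support = 4.0 * sigma_t;
  const PulseTable pt(fc, sigma_t);
  NumericVector sumsq(P);
  std::vector<double> t_arr(E), amp(E);

  for (int p = 0; p < P; ++p) {
    const double x = px[p], y = py[p], z = pz[p];
    double tmin = R_PosInf, tmax = R_NegInf;
    for (int e = 0; e < E; ++e) {
      const double dx = x - elem(e, 0), dy = y - elem(e, 1),
                   dz = z - elem(e, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      t_arr[e] = delays[e] + d / c;
      double lx, lz;
      elem_frame(normals(e, 0), normals(e, 2), &lx, &lz);
      const double ux = (dx * lx + dz * lz) / d;
      const double uy = dy / d;
      const double un = (dx * normals(e, 0) + dy * normals(e, 1) +
                         dz * normals(e, 2)) / d;
      amp[e] = apod[e] * directivity(ux, uy, un, width, length, lambda) /
               std::max(d, 1e-6);
      if (t_arr[e] < tmin) tmin = t_arr[e];
      if (t_arr[e] > tmax) tmax = t_arr[e];
    }
    const int i0 = (int)std::floor((tmin - support) * fs);
    const int i1 = (int)std::ceil((tmax + support) * fs);
    double acc = 0.0;
    for (int i = i0; i <= i1; ++i) {
      const double t = i / fs;
      double ysum = 0.0;
      for (int e = 0; e < E; ++e) {
        if (amp[e] == 0.0) continue;
        ysum += amp[e] * pt(t - t_arr[e]);
      }
      acc += ysum * ysum;
    }
    sumsq[p] = acc;
  }
  return sumsq;
}
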