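#include <Rcpp.h>
using namespace Rcpp;

// linear interpolation on a uniform grid starting at 0 with spacing dt
static inline double gridval(const NumericVector &g, double t, double dt) {
  double x = t / dt;
  int n = g.size();
  if (x <= 0) return g[0];
  int i = (int)x;
  if (i >= n - 1) return g[n - 1];
  double f = x - i;
  return g[i] * (1 - f) + g[i + 1] * f;
}

// Sequential beat-stream generator. Slowly varying profiles (baseline MAP,
// heart rate, LF amplitude, wander SD, coupling gain) come in as uniform
// lookup grids; per-beat noise comes in as pre-drawn vectors so the result
// is a deterministic function of the R RNG state. The pulse interval of
// beat i + delay responds to the SBP excursion of beat i with slope +brg
// (reflex bradycardia), and beat times accumulate those intervals exactly.
// [[Rcpp::export(name = ".gen_beat_stream")]]
List gen_beat_stream(double dur, double t0, double grid_dt,
                     NumericVector map0, NumericVector hr0,
                     NumericVector lfamp, NumericVector wander_sd,
                     NumericVector brg0,
                     double lf_freq, double hf_amp, double hf_freq,
                     double noise_sd, double pi_noise_sd, double pp2,
                     NumericVector eps, NumericVector eta, NumericVector u,
                     int delay) {
  int n_max = eps.size();
  std::vector<double> t, sbp, mapv, pint;
  t.reserve(n_max);
  std::vector<double> cpl_buf(delay > 0 ? delay : 1, 0.0);
  double ti = t0;
  const double two_pi = 2.0 * M_PI;
  for (int i = 0; i < n_max; ++i) {
    double w = gridval(wander_sd, ti, grid_dt) * u[i];
    double m = gridval(map0, ti, grid_dt) + w;
    double dev = gridval(lfamp, ti, grid_dt) * sin(two_pi * lf_freq * ti) +
                 hf_amp * sin(two_pi * hf_freq * ti) + noise_sd * eps[i];
    if (dev > 0.9 * pp2) dev = 0.9 * pp2;
    if (dev < -0.9 * pp2) dev = -0.9 * pp2;
    double cpl = dev + w;
    double src;
    if (delay > 0) {
      src = (i >= delay) ? cpl_buf[i % delay] : 0.0;
      cpl_buf[i % delay] = cpl;
    } else {
      src = cpl;
    }
    double pi_ms = 60000.0 / gridval(hr0, ti, grid_dt) +
                   gridval(brg0, ti, grid_dt) * src + pi_noise_sd * eta[i];
    if (pi_ms < 120.0) pi_ms = 120.0;
    if (pi_ms > 300.0) pi_ms = 300.0;
    if (ti + pi_ms / 1000.0 > dur) break;
    t.push_back(ti);
    sbp.push_back(m + pp2 + dev);
    mapv.push_back(m);
    pint.push_back(pi_ms);
    ti += pi_ms / 1000.0;
  }
  return List::create(_["t"] = t, _["sbp"] = sbp, _["map"] = mapv,
                      _["pint"] = pint);
}
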