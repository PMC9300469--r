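#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Drive waveform codes shared with R/landscape.R (.waveform_codes):
// 0 = off, 1 = square, 2 = smoothed (standard Fourier), 3 = smoothed (printed
// partial sum), 4 = dc.
static inline double waveform_value(int code, double t_local, double period, int n_terms) {
  switch (code) {
  case 0: return 0.0;
  case 4: return 1.0;
  case 1: {
    double phase = t_local - period * std::floor(t_local / period);
    return (phase < 0.5 * period) ? 1.0 : -1.0;
  }
  case 2: {
    double s = 0.0;
    for (int n = 1; n <= n_terms; n += 2)
      s += std::sin(2.0 * M_PI * n * t_local / period) / n;
    return 4.0 * s / M_PI;
  }
  case 3: {
    double s = 0.0;
    for (int n = 1; n <= n_terms; ++n)
      s += std::sin(n * t_local / period) / n;
    return s;
  }
  default: stop("unknown waveform code");
  }
  return 0.0;
}

// dU/dtheta of the switching landscape: field term plus periodic Gaussian
// wells (image sum truncated at n_images wells either side of the nearest
// well, enough for < 1e-12 truncation error).
static inline double grad_U(double theta, double Efield, double axis, double amp,
                            double a, double b, double c,
                            double theta0, double spacing, int n_images) {
  double g = -(4.0 * a / M_PI) * std::sin(theta - axis) * Efield * amp;
  double k0 = std::round((theta - theta0) / spacing);
  for (int j = -n_images; j <= n_images; ++j) {
    double x = theta - theta0 - (k0 + j) * spacing;
    g += 2.0 * b * c * x * std::exp(-c * x * x);
  }
  return g;
}

// [[Rcpp::export]]
double grad_potential_cpp(double theta, double Efield, double axis, double amp,
                          double a, double b, double c,
                          double theta0, double spacing, int n_images) {
  return grad_U(theta, Efield, axis, amp, a, b, c, theta0, spacing, n_images);
}

// Euler-Maruyama integration of lambda * dtheta/dt = -dU/dtheta + eta(t),
// <eta eta'> = 2 kT lambda delta.  Noise comes from R's RNG (norm_rand), so
// set.seed() on the R side gives bit-identical trajectories.  The optional
// linear torsional spring adds -kappa * (theta - anchor) to the torque.
// Returns theta at steps 0, stride, 2*stride, ..., n_steps.
// [[Rcpp::export]]
NumericVector simulate_em_cpp(NumericVector seg_t_start, NumericVector seg_t_end,
                              IntegerVector seg_wave, NumericVector seg_period,
                              NumericVector seg_amp, NumericVector seg_axis,
                              IntegerVector seg_nterms,
                              double a, double b, double c, double theta0,
                              double spacing, int n_images,
                              double lambda, double kT, double dt, int stride,
                              double theta_init, int n_steps,
                              double kappa, double anchor) {
  const int n_rec = n_steps / stride + 1;
  NumericVector out(n_rec);
  double theta = theta_init;
  out[0] = theta;
  const double noise_amp = std::sqrt(2.0 * kT * dt / lambda);
  const int n_seg = seg_t_start.size();
  int seg = 0;
  RNGScope scope;
  for (int k = 0; k < n_steps; ++k) {
    double t = k * dt;
    while (seg < n_seg - 1 && t >= seg_t_end[seg]) ++seg;
    double E = waveform_value(seg_wave[seg], t - seg_t_start[seg],
                              seg_period[seg], seg_nterms[seg]);
    double g = grad_U(theta, E, seg_axis[seg], seg_amp[seg],
                      a, b, c, theta0, spacing, n_images);
    if (kappa > 0.0) g += kappa * (theta - anchor);
    theta += -(g / lambda) * dt + noise_amp * norm_rand();
    if (!std::isfinite(theta))
      stop("integration diverged (non-finite angle) at step %d", k + 1);
    if ((k + 1) % stride == 0) out[(k + 1) / stride] = theta;
  }
  return out;
}

// Product-Gaussian-kernel bivariate KDE evaluated at arbitrary points.
// Samples (x, y) carry weights w (binned-KDE support); the density is
// normalized by total_weight, which callers set to the weight of the
// *unreplicated* sample so that periodic replicas in x do not inflate the
// density in the fundamental domain.
// [[Rcpp::export]]
NumericVector kde2_eval_cpp(NumericVector x, NumericVector y, NumericVector w,
                            double bw_x, double bw_y,
                            NumericVector eval_x, NumericVector eval_y,
                            double total_weight) {
  const int n = x.size(), m = eval_x.size();
  NumericVector out(m);
  const double norm = 1.0 / (2.0 * M_PI * bw_x * bw_y * total_weight);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    const double ex = eval_x[j], ey = eval_y[j];
    for (int i = 0; i < n; ++i) {
      double u = (ex - x[i]) / bw_x;
      double v = (ey - y[i]) / bw_y;
      double q = u * u + v * v;
      if (q < 50.0) s += w[i] * std::exp(-0.5 * q);
    }
    out[j] = s * norm;
  }
  return out;
}
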