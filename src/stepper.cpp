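// Euler-Maruyama stepping of the hierarchical tactile-rivalry model.
//
// The dynamics step at dt; storage is strided. All rate-like variables are
// updated as convex combinations (dt <= tau), so [0,1] is forward-invariant
// exactly, not just up to tolerance.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sigm(double x) {
  // overflow-safe logistic
  if (x >= 0.0) {
    return 1.0 / (1.0 + std::exp(-x));
  } else {
    double e = std::exp(x);
    return e / (1.0 + e);
  }
}

// smoothing of a raw waveform level: 0 = raw/ideal, 1 = printed sigmoid
// centred at 0, 2 = sigmoid centred at 1/2
static inline double smooth_level(double i, int mode, double k) {
  switch (mode) {
  case 1:  return sigm(k * i);
  case 2:  return sigm(k * (i - 0.5));
  default: return i;
  }
}

struct Stim {
  double delta_I, TD, TR, low;
  // raw antiphase square-wave levels; right side high on [2kTR, 2kTR+TD)
  inline void levels(double t, double &iR, double &iL) const {
    const double eps = 1e-9;   // robust half-open boundaries
    double per = 2.0 * TR;
    double ph = t - std::floor(t / per + eps) * per;
    iR = 0.0; iL = 0.0;
    if (ph < TD - eps) {
      iR = 1.0; iL = low;
    } else if (ph >= TR - eps && ph < TR + TD - eps) {
      iR = low; iL = 1.0;
    }
  }
};

struct Pars {
  double w, g, tau_nu, tau_alpha, x0, k_A, nu0, w_pool;
  double a, b, c, d, tau, tau_i, theta, alpha_x, beta_x, theta_s, k_H;
  bool heaviside, adapt_pool;
  inline double N(double x) const { return sigm(x - x0); }
  inline double A(double nu) const { return sigm(k_A * (nu - nu0)); }
  inline double S(double x) const {
    if (heaviside) return x >= 0.0 ? 1.0 : 0.0;
    return sigm(k_H * x);
  }
};

static Pars read_pars(const List &p) {
  Pars q;
  q.w = p["w"]; q.g = p["g"]; q.tau_nu = p["tau_nu"];
  q.w_pool = p.containsElementNamed("w_pool") ? as<double>(p["w_pool"]) : 0.0;
  q.adapt_pool = p.containsElementNamed("adapt_pool") ? as<bool>(p["adapt_pool"]) : true;
  q.tau_alpha = p["tau_alpha"]; q.x0 = p["x0"]; q.k_A = p["k_A"];
  q.nu0 = p["nu0"];
  q.a = p["a"]; q.b = p["b"]; q.c = p["c"]; q.d = p["d"];
  q.tau = p["tau"]; q.tau_i = p["tau_i"]; q.theta = p["theta"];
  q.alpha_x = p["alpha_x"]; q.beta_x = p["beta_x"];
  q.theta_s = p["theta_s"]; q.k_H = p["k_H"];
  q.heaviside = as<bool>(p["heaviside"]);
  return q;
}

static inline void bad_state(int k, double t) {
  stop("non-finite state at step %d (t = %.6f s); aborting integration", k, t);
}

// [[Rcpp::export(name = ".sim_full_cpp")]]
List sim_full_cpp(List pars, double delta_I, double TD, double TR,
                  double f_value, int drive_mode, double drive_offset,
                  int input_mode, double k_slope,
                  double sigma, double tau_n, bool shared_noise,
                  bool rate_convention,
                  double t_max, double dt, int stride,
                  NumericVector init, double clamp_nu) {
  Pars P = read_pars(pars);
  Stim st; st.delta_I = delta_I; st.TD = TD; st.TR = TR;
  st.low = 1.0 - delta_I;

  const int n_steps = (int)std::floor(t_max / dt + 1e-9);
  const int n_keep = n_steps / stride + 1;
  NumericMatrix out(n_keep, 14);

  double nuR = init[0], nuL = init[1], aR = init[2], aL = init[3];
  double uR = init[4], uL = init[5], yR = init[6], yL = init[7];
  double xR = init[8], xL = init[9];
  double zR = 0.0, zL = 0.0;

  const bool clamp = R_finite(clamp_nu);
  if (clamp) { nuR = clamp_nu; nuL = clamp_nu; }

  const bool noisy = sigma > 0.0;
  double ou_decay, ou_sd;
  if (rate_convention) {          // Eq. as printed: d z = -tau_n z dt + ...
    ou_decay = tau_n * dt;
    ou_sd = sigma * std::sqrt(2.0 * tau_n * dt);
  } else {                        // tau_n read as correlation time (default)
    ou_decay = dt / tau_n;
    ou_sd = sigma * std::sqrt(2.0 * dt / tau_n);
  }

  int row = 0;
  for (int k = 0; k <= n_steps; ++k) {
    double t = k * dt;
    double iR, iL;
    st.levels(t, iR, iL);

    if (k % stride == 0 && row < n_keep) {
      out(row, 0) = t;
      out(row, 1) = nuR;  out(row, 2) = nuL;
      out(row, 3) = aR;   out(row, 4) = aL;
      out(row, 5) = uR;   out(row, 6) = uL;
      out(row, 7) = yR;   out(row, 8) = yL;
      out(row, 9) = xR;   out(row, 10) = xL;
      out(row, 11) = zR;  out(row, 12) = iR; out(row, 13) = iL;
      ++row;
    }
    if (k == n_steps) break;

    // first-stage drive from (possibly smoothed) waveforms; the antiphase
    // component is the normalized contra-ipsi difference, the `drive_offset`
    // fraction adds the cycle-symmetric component f(dI) under which the
    // symmetric pair reduces exactly to the one-unit model with D = f(dI)
    double drv;
    if (delta_I == 0.0 || drive_mode == 3) {
      drv = 0.0;                 // 0/0 limit convention, or collapsed drive
    } else {
      double sR = smooth_level(iR, drive_mode, k_slope);
      double sL = smooth_level(iL, drive_mode, k_slope);
      drv = f_value * (sL - sR) / delta_I;
    }
    double drvR = drive_offset * f_value + drv;
    double drvL = drive_offset * f_value - drv;
    // second-stage inputs
    double cR = smooth_level(iR, input_mode, k_slope);
    double cL = smooth_level(iL, input_mode, k_slope);

    double inh = P.d * (nuR + nuL);
    // adaptation drive: population mean (default; reduces exactly to the
    // one-unit model's A(nu) under the symmetric collapse) or per-unit rate
    double adrvR = P.adapt_pool ? 0.5 * (nuR + nuL) : nuR;
    double adrvL = P.adapt_pool ? 0.5 * (nuR + nuL) : nuL;
    double nuR_n, nuL_n, aR_n, aL_n;
    if (clamp) {
      nuR_n = clamp_nu; nuL_n = clamp_nu;
      aR_n = aR + dt * (-aR + P.A(adrvR)) / P.tau_alpha;
      aL_n = aL + dt * (-aL + P.A(adrvL)) / P.tau_alpha;
    } else {
      // recurrent excitation mixed across the two first-stage units:
      // w_pool = 0 is per-unit self-excitation, w_pool = 0.5 symmetric
      // population pooling (each unit sees the population mean). Any value
      // reduces exactly to the one-unit simplified model when nu_R == nu_L.
      double excR = P.w * ((1.0 - P.w_pool) * nuR + P.w_pool * nuL);
      double excL = P.w * ((1.0 - P.w_pool) * nuL + P.w_pool * nuR);
      nuR_n = nuR + dt * (-nuR + P.N(excR - P.g * aR + drvR + zR)) / P.tau_nu;
      nuL_n = nuL + dt * (-nuL + P.N(excL - P.g * aL + drvL + zL)) / P.tau_nu;
      aR_n = aR + dt * (-aR + P.A(adrvR)) / P.tau_alpha;
      aL_n = aL + dt * (-aL + P.A(adrvL)) / P.tau_alpha;
    }
    double uR_n = uR + dt * (-uR + P.S(P.a * uL - P.b * xL - inh + P.c * cR - P.theta)) / P.tau;
    double uL_n = uL + dt * (-uL + P.S(P.a * uR - P.b * xR - inh + P.c * cL - P.theta)) / P.tau;
    double yR_n = yR + dt * (P.alpha_x * (1.0 - yR) * P.S(uR - P.theta) - P.beta_x * yR);
    double yL_n = yL + dt * (P.alpha_x * (1.0 - yL) * P.S(uL - P.theta) - P.beta_x * yL);
    double xR_n = xR + dt * (-xR + P.S(yR - P.theta_s)) / P.tau_i;
    double xL_n = xL + dt * (-xL + P.S(yL - P.theta_s)) / P.tau_i;

    nuR = nuR_n; nuL = nuL_n; aR = aR_n; aL = aL_n;
    uR = uR_n; uL = uL_n; yR = yR_n; yL = yL_n; xR = xR_n; xL = xL_n;

    if (noisy) {
      double eta = norm_rand();
      zR += -ou_decay * zR + ou_sd * eta;
      if (shared_noise) {
        zL = zR;
      } else {
        zL += -ou_decay * zL + ou_sd * norm_rand();
      }
    }

    if (!(std::isfinite(nuR) && std::isfinite(uR) && std::isfinite(xR) &&
          std::isfinite(nuL) && std::isfinite(uL) && std::isfinite(xL)))
      bad_state(k + 1, t + dt);
    if ((k & 0x3FFFF) == 0) Rcpp::checkUserInterrupt();
  }

  colnames(out) = CharacterVector::create(
    "t", "nu_R", "nu_L", "alpha_R", "alpha_L", "u_R", "u_L",
    "y_R", "y_L", "x_R", "x_L", "zeta", "i_R", "i_L");
  return List::create(_["states"] = out, _["n_steps"] = n_steps);
}

// [[Rcpp::export(name = ".sim_simplified_cpp")]]
List sim_simplified_cpp(List pars, double D, double nu_weight,
                        double delta_I, double TD, double TR,
                        int input_mode, double k_slope,
                        double sigma, double tau_n, bool rate_convention,
                        double t_max, double dt, int stride,
                        NumericVector init) {
  Pars P = read_pars(pars);
  Stim st; st.delta_I = delta_I; st.TD = TD; st.TR = TR;
  st.low = 1.0 - delta_I;

  const int n_steps = (int)std::floor(t_max / dt + 1e-9);
  const int n_keep = n_steps / stride + 1;
  NumericMatrix out(n_keep, 12);

  double nu = init[0], al = init[1];
  double uR = init[2], uL = init[3], yR = init[4], yL = init[5];
  double xR = init[6], xL = init[7];
  double z = 0.0;

  const bool noisy = sigma > 0.0;
  double ou_decay, ou_sd;
  if (rate_convention) {
    ou_decay = tau_n * dt;
    ou_sd = sigma * std::sqrt(2.0 * tau_n * dt);
  } else {
    ou_decay = dt / tau_n;
    ou_sd = sigma * std::sqrt(2.0 * dt / tau_n);
  }

  int row = 0;
  for (int k = 0; k <= n_steps; ++k) {
    double t = k * dt;
    double iR, iL;
    st.levels(t, iR, iL);

    if (k % stride == 0 && row < n_keep) {
      out(row, 0) = t;
      out(row, 1) = nu; out(row, 2) = al;
      out(row, 3) = uR; out(row, 4) = uL;
      out(row, 5) = yR; out(row, 6) = yL;
      out(row, 7) = xR; out(row, 8) = xL;
      out(row, 9) = z;  out(row, 10) = iR; out(row, 11) = iL;
      ++row;
    }
    if (k == n_steps) break;

    double cR = smooth_level(iR, input_mode, k_slope);
    double cL = smooth_level(iL, input_mode, k_slope);
    double inh = nu_weight * P.d * nu;

    double nu_n = nu + dt * (-nu + P.N(P.w * nu - P.g * al + D + z)) / P.tau_nu;
    double al_n = al + dt * (-al + P.A(nu)) / P.tau_alpha;
    double uR_n = uR + dt * (-uR + P.S(P.a * uL - P.b * xL - inh + P.c * cR - P.theta)) / P.tau;
    double uL_n = uL + dt * (-uL + P.S(P.a * uR - P.b * xR - inh + P.c * cL - P.theta)) / P.tau;
    double yR_n = yR + dt * (P.alpha_x * (1.0 - yR) * P.S(uR - P.theta) - P.beta_x * yR);
    double yL_n = yL + dt * (P.alpha_x * (1.0 - yL) * P.S(uL - P.theta) - P.beta_x * yL);
    double xR_n = xR + dt * (-xR + P.S(yR - P.theta_s)) / P.tau_i;
    double xL_n = xL + dt * (-xL + P.S(yL - P.theta_s)) / P.tau_i;

    nu = nu_n; al = al_n; uR = uR_n; uL = uL_n;
    yR = yR_n; yL = yL_n; xR = xR_n; xL = xL_n;

    if (noisy) {
      z += -ou_decay * z + ou_sd * norm_rand();
    }

    if (!(std::isfinite(nu) && std::isfinite(uR) && std::isfinite(uL) &&
          std::isfinite(xR) && std::isfinite(xL)))
      bad_state(k + 1, t + dt);
    if ((k & 0x3FFFF) == 0) Rcpp::checkUserInterrupt();
  }

  colnames(out) = CharacterVector::create(
    "t", "nu", "alpha", "u_R", "u_L", "y_R", "y_L", "x_R", "x_L",
    "zeta", "i_R", "i_L");
  return List::create(_["states"] = out, _["n_steps"] = n_steps);
}

// [[Rcpp::export(name = ".ou_path_cpp")]]
NumericVector ou_path_cpp(double sigma, double tau_n, double dt, int n_steps,
                          bool rate_convention) {
  NumericVector z(n_steps + 1);
  double ou_decay, ou_sd;
  if (rate_convention) {
    ou_decay = tau_n * dt;
    ou_sd = sigma * std::sqrt(2.0 * tau_n * dt);
  } else {
    ou_decay = dt / tau_n;
    ou_sd = sigma * std::sqrt(2.0 * dt / tau_n);
  }
  double cur = 0.0;
  z[0] = 0.0;
  if (sigma <= 0.0) return z;
  for (int k = 1; k <= n_steps; ++k) {
    cur += -ou_decay * cur + ou_sd * norm_rand();
    z[k] = cur;
  }
  return z;
}
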