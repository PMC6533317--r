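#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Input-output transfer function of the sensorimotor populations:
//   H(x) = (a*x - b) / (1 - exp(-d*(a*x - b)))
// with the removable singularity at a*x = b handled by a series expansion
// (limit 1/d). Guards against exp overflow for strongly hyperpolarising input.
static inline double transfer(double x, double a, double b, double d) {
  const double z = a * x - b;      // Hz
  const double u = d * z;          // dimensionless
  if (std::fabs(u) < 1e-4)
    return (1.0 / d) * (1.0 + 0.5 * u + u * u / 12.0);
  if (u > 30.0) return z;          // exp(-u) negligible
  if (u < -30.0) return -z * std::exp(u); // ~0, avoids overflow of exp(-u)
  return z / (1.0 - std::exp(-u));
}

// [[Rcpp::export]]
double engine_transfer(double x, double a, double b, double d) {
  return transfer(x, a, b, d);
}

static inline double relu(double v) { return v > 0.0 ? v : 0.0; }

// Integrate one trial of the full circuit with the forward Euler-Maruyama
// scheme. Noise is drawn from R's RNG (norm_rand), so seeding with set.seed()
// before the call makes the trial fully reproducible.
//
// par: named list of model constants (see model_parameters()).
// cfg: named list with epsilon, correct_side (1|2), t_stimulus_onset,
//      t_timeout, delay_inh, delay_unc, dt, mu_eff (effective tonic bias,
//      already including any coupled-trial increment).
// record: if true, return the full state trace on the integration grid.
//
// Events implemented:
//  (i)   top-down inhibition g at g_baseline on both uncertainty populations
//        and the motor populations from trial start;
//  (ii)  stimulus currents on from t_stimulus_onset;
//  (iii) g removed from the inhibitory population delay_inh after stimulus
//        onset and from the uncertainty-encoding population delay_unc after;
//  (iv)  when max(H1,H2) first reaches decision_threshold: record the
//        response time and initial choice, reinstate g at g_reactivated on
//        the uncertainty module and release the motor module;
//  (v)   integrate on (no reset of any state variable) until a motor rate
//        reaches M_th (final choice) or t_timeout after stimulus onset
//        (indecision).
// [[Rcpp::export]]
List engine_run_trial(List par, List cfg, bool record) {
  // --- model constants ---
  const double a        = as<double>(par["a"]);
  const double b        = as<double>(par["b"]);
  const double d        = as<double>(par["d"]);
  const double gamma_   = as<double>(par["gamma"]);
  const double tau_s    = as<double>(par["tau_s"]);       // ms
  const double JNs      = as<double>(par["J_N_self"]);
  const double JNc      = as<double>(par["J_N_cross"]);
  const double I0       = as<double>(par["I0"]);
  const double JAext    = as<double>(par["J_A_ext"]);
  const double mu0      = as<double>(par["mu0"]);
  const double Jmc0     = as<double>(par["J_mc0"]);
  const double tau_mc   = as<double>(par["tau_mc"]);      // ms
  const double JVinh    = as<double>(par["J_V_inh"]);
  const double JNinh    = as<double>(par["J_N_inh"]);
  const double g_base   = as<double>(par["g_baseline"]);
  const double g_react  = as<double>(par["g_reactivated"]);
  const double tau_h    = as<double>(par["tau_h"]);       // ms
  const double Jmotor   = as<double>(par["J_motor"]);
  const double JNLR     = as<double>(par["J_N_LR"]);
  const double JNRL     = as<double>(par["J_N_RL"]);
  const double Tpos     = as<double>(par["T_pos"]);
  const double Mth      = as<double>(par["M_th"]);
  const double thr      = as<double>(par["decision_threshold"]);
  const double sigma    = as<double>(par["sigma_noise"]);
  const double tau_n    = as<double>(par["tau_noise"]);   // ms
  const double S_init   = as<double>(par["S_init"]);
  const double q        = std::fabs(Tpos) / Mth;

  // --- protocol ---
  const double eps      = as<double>(cfg["epsilon"]);     // percent, >= 0
  const int    corr     = as<int>(cfg["correct_side"]);   // 1 or 2
  const double t_stim   = as<double>(cfg["t_stimulus_onset"]);
  const double t_out    = as<double>(cfg["t_timeout"]);   // after stimulus
  const double del_inh  = as<double>(cfg["delay_inh"]);
  const double del_unc  = as<double>(cfg["delay_unc"]);
  const double dt       = as<double>(cfg["dt"]);
  const double mu_eff   = as<double>(cfg["mu_eff"]);      // tonic bias, nA

  const double t_end = t_stim + t_out;
  const int n_max = (int)std::floor(t_end / dt + 0.5);

  // stimulus currents (population 1 preferred iff correct_side == 1)
  const double Ip = JAext * mu0 * (1.0 + eps / 100.0);
  const double In = JAext * mu0 * (1.0 - eps / 100.0);
  const double I1_on = (corr == 1) ? Ip : In;
  const double I2_on = (corr == 1) ? In : Ip;

  // --- state ---
  double S1 = S_init, S2 = S_init;
  double In1 = 0.0, In2 = 0.0;     // Ornstein-Uhlenbeck noise currents, nA
  double y_inh = 0.0, y_U = 0.0, y_L = 0.0, y_R = 0.0;

  // --- events/summaries ---
  bool decided = false, tie = false;
  double rt = NA_REAL;
  int initial_choice = 0, final_choice = 0;
  int first_sign = 0;              // sign of x when movement first departs 0
  bool sign_changed = false;       // x visited the side opposite first_sign
  double yU_peak = 0.0, yU_area = 0.0;   // area: Hz*ms, trapezoidal
  bool reached = false;

  const double noise_k = sigma * std::sqrt(dt / tau_n);
  const double ou_k = dt / tau_n;

  NumericMatrix tr;
  if (record) tr = NumericMatrix(n_max + 1, 10);

  int i = 0;
  double yU_prev = y_U;
  for (i = 0; i <= n_max; ++i) {
    const double t = i * dt;
    const bool stim_on = (t >= t_stim);

    const double x1 = JNs * S1 - JNc * S2 + I0 + (stim_on ? I1_on : 0.0)
                      + Jmc0 * y_U + In1;
    const double x2 = JNs * S2 - JNc * S1 + I0 + (stim_on ? I2_on : 0.0)
                      + Jmc0 * y_U + In2;
    const double H1 = transfer(x1, a, b, d);
    const double H2 = transfer(x2, a, b, d);

    // decision detection on the discrete grid (first step at/over threshold)
    if (!decided && (H1 >= thr || H2 >= thr)) {
      decided = true;
      rt = t - t_stim;
      if (H1 >= thr && H2 >= thr && H1 == H2) { initial_choice = 1; tie = true; }
      else initial_choice = (H1 >= H2) ? 1 : 2;
    }

    const double xpos = q * (y_L - y_R);
    if (decided && first_sign == 0 && xpos != 0.0)
      first_sign = (xpos > 0.0) ? 1 : -1;
    if (first_sign != 0 && !sign_changed &&
        ((first_sign > 0 && xpos < 0.0) || (first_sign < 0 && xpos > 0.0)))
      sign_changed = true;

    if (record) {
      tr(i, 0) = t;   tr(i, 1) = S1;   tr(i, 2) = S2;
      tr(i, 3) = H1;  tr(i, 4) = H2;   tr(i, 5) = y_inh;
      tr(i, 6) = y_U; tr(i, 7) = y_L;  tr(i, 8) = y_R; tr(i, 9) = xpos;
    }

    if (yU_peak < y_U) yU_peak = y_U;
    if (i > 0) yU_area += 0.5 * (yU_prev + y_U) * dt;
    yU_prev = y_U;

    // motor target check (final choice)
    if (decided && (y_L >= Mth || y_R >= Mth)) {
      reached = true;
      final_choice = (y_L >= Mth && y_L >= y_R) ? 1 : 2;
      break;
    }
    if (i == n_max) break;  // timeout

    // gating amplitudes for this step's derivatives
    const double g_inh = decided ? g_react
                         : ((t >= t_stim + del_inh) ? 0.0 : g_base);
    const double g_unc = decided ? g_react
                         : ((t >= t_stim + del_unc) ? 0.0 : g_base);
    const double g_mot = decided ? 0.0 : g_base;

    // Euler-Maruyama update (times in ms; H in Hz so gamma*H is per second)
    const double dS1 = -S1 / tau_s + (1.0 - S1) * gamma_ * H1 * 1e-3;
    const double dS2 = -S2 / tau_s + (1.0 - S2) * gamma_ * H2 * 1e-3;
    S1 += dt * dS1;
    S2 += dt * dS2;
    In1 += -ou_k * In1 + noise_k * norm_rand();
    In2 += -ou_k * In2 + noise_k * norm_rand();
    y_inh += (dt / tau_mc) * (relu(JVinh * (H1 + H2) - g_inh) - y_inh);
    y_U   += (dt / tau_mc) * (relu(mu_eff - JNinh * y_inh - g_unc) - y_U);
    const double yLn = y_L + (dt / tau_h) * (relu(Jmotor * H1 - JNLR * y_R - g_mot) - y_L);
    const double yRn = y_R + (dt / tau_h) * (relu(Jmotor * H2 - JNRL * y_L - g_mot) - y_R);
    y_L = yLn; y_R = yRn;

    if (!std::isfinite(S1 + S2 + In1 + In2 + y_inh + y_U + y_L + y_R))
      stop("non-finite network state at step %d (t = %.2f ms)", i + 1,
           (i + 1) * dt);
  }

  const bool indecision = !reached;
  // change-of-mind: reversal of the order of dominance of the motor
  // populations — the final choice differs from the initial movement
  // direction — with a choice target eventually reached
  const int final_sign = reached ? (final_choice == 1 ? 1 : -1) : 0;
  const bool com = reached && first_sign != 0 && final_sign != first_sign;
  int com_dir = 0; // 0 none, 1 error-to-correct, 2 correct-to-error
  if (com) com_dir = (final_choice == corr) ? 1 : 2;

  List ev = List::create(
    _["rt"] = rt,
    _["initial_choice"] = initial_choice,
    _["final_choice"] = final_choice,
    _["indecision"] = indecision,
    _["com"] = com,
    _["com_direction"] = com_dir,
    _["first_move_sign"] = first_sign,
    _["sign_changed"] = sign_changed,
    _["uncertainty_peak"] = yU_peak,
    _["uncertainty_area"] = yU_area,
    _["t_end"] = i * dt,
    _["tie"] = tie);

  if (record) {
    NumericMatrix out(i + 1, 10);
    for (int r = 0; r <= i; ++r)
      for (int c = 0; c < 10; ++c) out(r, c) = tr(r, c);
    colnames(out) = CharacterVector::create(
      "time", "S1", "S2", "H1", "H2", "y_inh", "y_U", "y_L", "y_R", "x");
    return List::create(_["events"] = ev, _["trace"] = out);
  }
  return List::create(_["events"] = ev, _["trace"] = R_NilValue);
}
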