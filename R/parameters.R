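#' Model parameters for the decision-uncertainty circuit
#'
#' Builds the full set of circuit constants, in physical units, for the
#' three-module network: a reduced two-variable sensorimotor module (slow
#' NMDA-mediated synaptic gating variables `S1`, `S2`), an
#' uncertainty-monitoring microcircuit (an inhibitory population `y_inh`
#' driven by the summed sensorimotor rates, inhibiting an
#' uncertainty-encoding population `y_U` whose activity is fed back equally
#' to both sensorimotor populations), and a pair of mutually inhibitory
#' motor integrators (`y_L`, `y_R`) whose difference maps linearly onto a
#' screen position.
#'
#' All currents are in nA, rates in Hz and times in ms. The sensorimotor
#' constants default to the published reduced two-variable mean-field model
#' they are taken from; the uncertainty- and motor-module couplings default
#' to the package's calibrated profile (see the methods vignette).
#'
#' @param ... named overrides of any default constant.
#'
#' @section Fields:
#' \describe{
#'   \item{a, b, d}{input-output function gain (Hz/nA), threshold (Hz) and
#'     curvature (s) of the transfer function [transfer_H()].}
#'   \item{gamma, tau_s}{synaptic gating kinetic constant (dimensionless)
#'     and NMDA gating time constant (ms).}
#'   \item{J_N_self, J_N_cross}{recurrent self- and cross-couplings (nA).}
#'   \item{I0}{background current (nA).}
#'   \item{J_A_ext, mu0}{external synaptic coupling (nA/Hz) and stimulus
#'     strength (Hz); the stimulus current is
#'     `J_A_ext * mu0 * (1 +/- epsilon/100)`.}
#'   \item{J_mc0}{coupling of the uncertainty feedback current (nA per unit
#'     of `y_U`), applied equally to both sensorimotor populations.}
#'   \item{tau_mc, J_V_inh, J_N_inh, mu_tonic}{uncertainty-module time
#'     constant (ms), sensorimotor-to-inhibitory coupling, inhibitory-to-
#'     uncertainty coupling, and tonic bias current (nA).}
#'   \item{g_baseline, g_reactivated}{top-down inhibition amplitudes (nA):
#'     the clamp applied from trial start, and the stronger clamp reinstated
#'     on the uncertainty module once a decision is made.}
#'   \item{tau_h, J_motor, J_N_LR, J_N_RL}{motor time constant (ms),
#'     sensorimotor-to-motor coupling (nA/Hz), and mutual-inhibition
#'     couplings.}
#'   \item{T_pos, M_th}{choice-target position (screen units) and motor
#'     target threshold (Hz). The position scaling `q = T_pos / M_th` is
#'     always recomputed from these two, never stored.}
#'   \item{decision_threshold}{sensorimotor firing-rate threshold (Hz)
#'     defining the response time.}
#'   \item{sigma_noise, tau_noise}{amplitude (nA) and correlation time (ms)
#'     of the Ornstein-Uhlenbeck noise currents entering the sensorimotor
#'     populations.}
#'   \item{S_init}{spontaneous initial value of both gating variables.}
#' }
#'
#' @return an object of class `model_parameters` (a validated named list).
#' @examples
#' p <- model_parameters()
#' p$decision_threshold
#' p2 <- model_parameters(J_mc0 = 0)  # feedback-ablated circuit
#' @export
model_parameters <- function(...) {
  p <- default_parameters()
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(ov)] <- ov
  }
  validate_parameters(p)
}

# Default profile. Sensorimotor constants are the published reduced-model
# values; uncertainty/motor couplings are the package's calibrated profile.
default_parameters <- function() {
  list(
    # sensorimotor module
    a = 270, b = 108, d = 0.154,
    gamma = 0.641, tau_s = 100,
    J_N_self = 0.2609, J_N_cross = 0.0497,
    I0 = 0.3255, J_A_ext = 5.2e-4, mu0 = 30,
    decision_threshold = 35.5,
    # uncertainty feedback
    J_mc0 = 0.0072,
    # uncertainty-monitoring module
    tau_mc = 350, J_V_inh = 0.1, J_N_inh = 1, mu_tonic = 7,
    g_baseline = 1000, g_reactivated = 3000,
    # motor module
    tau_h = 300, J_motor = 1, J_N_LR = 2, J_N_RL = 2,
    T_pos = 750, M_th = 17.4,
    # noise
    sigma_noise = 0.0125, tau_noise = 12,
    # initial conditions
    S_init = 0.1
  )
}

validate_parameters <- function(p) {
  num1 <- function(nm) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
    as.numeric(v)
  }
  p <- stats::setNames(lapply(names(p), num1), names(p))
  pos <- c("tau_s", "tau_mc", "tau_h", "tau_noise", "d",
           "decision_threshold", "M_th")
  for (nm in pos)
    if (p[[nm]] <= 0) stop("parameter '", nm, "' must be > 0")
  nonneg <- c("g_baseline", "g_reactivated", "sigma_noise")
  for (nm in nonneg)
    if (p[[nm]] < 0) stop("parameter '", nm, "' must be >= 0")
  if (p$g_reactivated < p$g_baseline)
    stop("g_reactivated must be >= g_baseline")
  if (p$S_init < 0 || p$S_init > 1)
    stop("S_init must lie in [0, 1]")
  structure(p, class = "model_parameters")
}

#' Position scaling factor of the motor read-out
#'
#' The motor position is `x = q * (y_L - y_R)` with `q = |T_pos| / M_th`,
#' recomputed from the stored target position and motor threshold.
#'
#' @param params a [model_parameters()] object.
#' @return the scalar scaling factor q (screen units per Hz).
#' @export
position_scale <- function(params) abs(params$T_pos) / params$M_th

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>\n")
  cat(sprintf("  sensorimotor: a=%g b=%g d=%g gamma=%g tau_s=%g ms\n",
              x$a, x$b, x$d, x$gamma, x$tau_s))
  cat(sprintf("    J_N_self=%g J_N_cross=%g I0=%g J_A_ext=%g mu0=%g\n",
              x$J_N_self, x$J_N_cross, x$I0, x$J_A_ext, x$mu0))
  cat(sprintf("  uncertainty: J_mc0=%g tau_mc=%g ms J_V_inh=%g J_N_inh=%g mu_tonic=%g\n",
              x$J_mc0, x$tau_mc, x$J_V_inh, x$J_N_inh, x$mu_tonic))
  cat(sprintf("    gating g: baseline=%g reactivated=%g nA\n",
              x$g_baseline, x$g_reactivated))
  cat(sprintf("  motor: tau_h=%g ms J=%g J_N_LR=%g J_N_RL=%g T_pos=%g M_th=%g Hz\n",
              x$tau_h, x$J_motor, x$J_N_LR, x$J_N_RL, x$T_pos, x$M_th))
  cat(sprintf("  thresholds: decision=%g Hz; noise: sigma=%g nA tau=%g ms\n",
              x$decision_threshold, x$sigma_noise, x$tau_noise))
  invisible(x)
}

# stable content hash of a parameter profile (used in manifests)
parameter_hash <- function(params) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(names(params), vapply(params, format, "",
                                         digits = 17), sep = "="), f)
  unname(tools::md5sum(f))
}
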