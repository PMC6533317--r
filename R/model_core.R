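#' Single-cell input-output transfer function
#'
#' Firing rate of a sensorimotor population as a function of its total
#' synaptic current, `H(x) = (a x - b) / (1 - exp(-d (a x - b)))`, the
#' standard fit to a leaky integrate-and-fire neuron. The removable
#' singularity at `a x = b` is evaluated by its analytic limit `1/d`.
#'
#' @param x total synaptic current (nA); vectorised.
#' @param params a [model_parameters()] object.
#' @return firing rate(s) in Hz (non-negative, increasing in `x`).
#' @examples
#' p <- model_parameters()
#' transfer_H(0.5, p)
#' transfer_H(p$b / p$a, p) * p$d  # == 1 at the singular point
#' @export
transfer_H <- function(x, params) {
  if (!all(is.finite(x))) stop("non-finite input current in transfer_H")
  z <- params$a * x - params$b
  u <- params$d * z
  near <- abs(u) < 1e-4
  H <- z / (1 - exp(-u))              # overflow of exp gives the 0 limit
  H[near] <- (1 / params$d) * (1 + u[near] / 2 + u[near]^2 / 12)
  H
}

#' Total synaptic current into a sensorimotor population
#'
#' `x_i = J_N_self S_i - J_N_cross S_j + I0 + I_stim + J_mc0 y_U + I_noise`.
#' The uncertainty feedback term `J_mc0 y_U` is identical for both
#' populations: uncertainty is fed back equally.
#'
#' @param S_self,S_other synaptic gating variables of this and the competing
#'   population, each in \[0, 1\].
#' @param I_stim stimulus current (nA), see [stimulus_current()].
#' @param y_U activity of the uncertainty-encoding population (>= 0).
#' @param I_noise additive Ornstein-Uhlenbeck noise current (nA).
#' @param params a [model_parameters()] object.
#' @return total current in nA.
#' @export
sensorimotor_current <- function(S_self, S_other, I_stim, y_U, I_noise,
                                 params) {
  stopifnot(all(is.finite(c(S_self, S_other, I_stim, y_U, I_noise))))
  params$J_N_self * S_self - params$J_N_cross * S_other +
    params$I0 + I_stim + params$J_mc0 * y_U + I_noise
}

#' Stimulus current for a given evidence quality
#'
#' `I = J_A_ext * mu0 * (1 +/- epsilon/100)`: the population selective for
#' the correct side receives the `+` sign. `epsilon` plays the role of
#' motion coherence in a random-dot stimulus; at `epsilon = 0` both
#' populations receive the same input.
#'
#' @param epsilon evidence quality in percent, in \[0, 100\].
#' @param preferred logical; `TRUE` for the population whose choice is
#'   correct on this trial.
#' @param params a [model_parameters()] object.
#' @return stimulus current in nA.
#' @export
stimulus_current <- function(epsilon, preferred, params) {
  if (!is.numeric(epsilon) || any(!is.finite(epsilon)) ||
      any(epsilon < 0) || any(epsilon > 100))
    stop("epsilon must lie in [0, 100]")
  s <- ifelse(preferred, 1 + epsilon / 100, 1 - epsilon / 100)
  params$J_A_ext * params$mu0 * s
}

#' Time derivatives of the uncertainty-monitoring module
#'
#' Threshold-linear dynamics of the inhibitory population (driven by the
#' summed sensorimotor rates) and of the uncertainty-encoding population
#' (driven by a tonic bias and inhibited by the former):
#' \deqn{\tau_{mc} \dot y_{inh} = [J_{V,inh}(H_1 + H_2) - g]_+ - y_{inh}}
#' \deqn{\tau_{mc} \dot y_U = [\mu - J_{N,inh} y_{inh} - g]_+ - y_U}
#' The rectification `[.]_+ = max(0, .)` applies to the full bracketed
#' drive, not to the derivative.
#'
#' @param y_inh,y_U current activities (>= 0).
#' @param H1,H2 sensorimotor population rates (Hz).
#' @param g_inh,g_exc top-down inhibition amplitudes (nA) currently applied
#'   to the inhibitory and uncertainty-encoding populations.
#' @param mu tonic bias current (nA) to the uncertainty-encoding population.
#' @param params a [model_parameters()] object.
#' @return numeric vector `c(dy_inh, dy_U)` in units of activity per ms.
#' @export
uncertainty_derivatives <- function(y_inh, y_U, H1, H2, g_inh, g_exc, mu,
                                    params) {
  d_inh <- (max(0, params$J_V_inh * (H1 + H2) - g_inh) - y_inh) / params$tau_mc
  d_u <- (max(0, mu - params$J_N_inh * y_inh - g_exc) - y_U) / params$tau_mc
  c(dy_inh = d_inh, dy_U = d_u)
}

#' Time derivatives of the motor populations
#'
#' Mirror-symmetric threshold-linear integrators with mutual inhibition,
#' each driven by one sensorimotor population:
#' \deqn{\tau_h \dot y_L = [J H_1 - J_{N,LR} y_R - g]_+ - y_L}
#' \deqn{\tau_h \dot y_R = [J H_2 - J_{N,RL} y_L - g]_+ - y_R}
#'
#' @param y_L,y_R motor population activities (>= 0).
#' @param H1,H2 sensorimotor population rates (Hz).
#' @param g_motor top-down inhibition amplitude (nA) currently applied.
#' @param params a [model_parameters()] object.
#' @return numeric vector `c(dy_L, dy_R)` in units of activity per ms.
#' @export
motor_derivatives <- function(y_L, y_R, H1, H2, g_motor, params) {
  d_L <- (max(0, params$J_motor * H1 - params$J_N_LR * y_R - g_motor) - y_L) /
    params$tau_h
  d_R <- (max(0, params$J_motor * H2 - params$J_N_RL * y_L - g_motor) - y_R) /
    params$tau_h
  c(dy_L = d_L, dy_R = d_R)
}

#' Motor position read-out
#'
#' Maps the motor activities onto a screen position,
#' `x = q (y_L - y_R)` with `q = |T_pos| / M_th`, so that `|x|` equals the
#' target position exactly when the leading population is at the motor
#' threshold with the other silent. The read-out is antisymmetric in
#' `(y_L, y_R)`.
#'
#' @param y_L,y_R motor population activities (Hz); vectorised.
#' @param params a [model_parameters()] object.
#' @return position in screen units.
#' @export
motor_position <- function(y_L, y_R, params) {
  position_scale(params) * (y_L - y_R)
}
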