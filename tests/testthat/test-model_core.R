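test_that("transfer function matches direct evaluation and its limits", {
  p <- params_default
  # direct arithmetic oracle at x = 0.5 nA: a*x - b = 27 Hz
  expect_equal(transfer_H(0.5, p), 27 / (1 - exp(-0.154 * 27)),
               tolerance = 1e-12)
  # removable singularity: H = 1/d at a*x = b
  expect_equal(transfer_H(p$b / p$a, p), 1 / p$d, tolerance = 1e-12)
  # strongly hyperpolarising input drives the rate to zero
  expect_lt(transfer_H(-5, p), 1e-12)
  expect_gte(transfer_H(-5, p), 0)
  # monotone increasing and non-negative over a wide current range
  xs <- seq(-1, 2, by = 0.01)
  H <- transfer_H(xs, p)
  expect_true(all(H >= 0))
  expect_true(all(diff(H) > 0))
  expect_error(transfer_H(NaN, p), "non-finite")
})

test_that("transfer function is continuous at the singular point", {
  p <- params_default
  x0 <- p$b / p$a
  series <- function(z) {
    u <- p$d * z
    (1 / p$d) * (1 + u / 2 + u^2 / 12 + u^4 / 720 * 0) # 3-term oracle
  }
  for (dz in c(1e-3, 1e-5, -1e-3, -1e-5)) {
    x <- x0 + dz / p$a
    expect_equal(transfer_H(x, p), series(dz), tolerance = 1e-9)
  }
})

test_that("sensorimotor current assembles the coupling terms", {
  p <- params_default
  # all couplings silent: background current only
  expect_equal(sensorimotor_current(0, 0, 0, 0, 0, p), p$I0)
  # both gating variables saturated
  expect_equal(sensorimotor_current(1, 1, 0, 0, 0, p),
               p$J_N_self - p$J_N_cross + p$I0)
  # uncertainty feedback is shared equally by both populations
  d <- 0.37
  x1 <- sensorimotor_current(0.2, 0.7, 0.01, d, 0, p)
  x2 <- sensorimotor_current(0.7, 0.2, 0.01, d, 0, p)
  expect_equal(x1 - sensorimotor_current(0.2, 0.7, 0.01, 0, 0, p),
               p$J_mc0 * d)
  expect_equal(x2 - sensorimotor_current(0.7, 0.2, 0.01, 0, 0, p),
               p$J_mc0 * d)
  # exchange symmetry of the pair
  expect_equal(sensorimotor_current(0.3, 0.6, 0, 0, 0, p),
               sensorimotor_current(0.3, 0.6, 0, 0, 0, p))
})

test_that("stimulus current scales with evidence quality", {
  p <- params_default
  base <- p$J_A_ext * p$mu0
  expect_equal(stimulus_current(0, TRUE, p), base)
  expect_equal(stimulus_current(0, FALSE, p), base)
  expect_equal(stimulus_current(100, FALSE, p), 0)
  expect_equal(stimulus_current(3.2, TRUE, p), base * 1.032)
  expect_error(stimulus_current(-1, TRUE, p), "\\[0, 100\\]")
  expect_error(stimulus_current(120, TRUE, p), "\\[0, 100\\]")
})

test_that("uncertainty-module derivatives rectify the bracketed drive", {
  p <- params_default
  # a clamp exceeding every excitatory drive leaves pure decay
  d <- uncertainty_derivatives(2, 3, 30, 30, 1e4, 1e4, p$mu_tonic, p)
  expect_equal(unname(d), c(-2 / p$tau_mc, -3 / p$tau_mc))
  # unclamped, uninhibited: y_U relaxes towards mu
  d <- uncertainty_derivatives(0, p$mu_tonic, 0, 0, 0, 0, p$mu_tonic, p)
  expect_equal(unname(d[2]), 0)
  # inhibitory drive is linear in the summed rates with slope J_V_inh/tau_mc
  d1 <- uncertainty_derivatives(0, 0, 10, 10, 0, 0, p$mu_tonic, p)
  d2 <- uncertainty_derivatives(0, 0, 15, 25, 0, 0, p$mu_tonic, p)
  expect_equal(unname(d2[1] - d1[1]), p$J_V_inh * 20 / p$tau_mc)
})

test_that("motor derivatives are mirror-symmetric rectified integrators", {
  p <- params_default
  d <- motor_derivatives(1.5, 2.5, 30, 30, 1e5, p)
  expect_equal(unname(d), c(-1.5 / p$tau_h, -2.5 / p$tau_h))
  # exchange symmetry from a symmetric state
  d <- motor_derivatives(2, 2, 20, 20, 0, p)
  expect_equal(unname(d[1]), unname(d[2]))
  # monotone in the driving rate
  dA <- motor_derivatives(2, 2, 25, 20, 0, p)
  expect_gt(unname(dA[1]), unname(dA[2]))
})

test_that("motor position mapping is antisymmetric and target-scaled", {
  p <- params_default
  expect_equal(motor_position(3.3, 3.3, p), 0)
  expect_equal(motor_position(17.4, 0, p), 750)
  expect_equal(motor_position(0, 17.4, p), -750)
  expect_equal(position_scale(p), abs(p$T_pos) / p$M_th)
})

test_that("parameter validation rejects inconsistent profiles", {
  expect_error(model_parameters(tau_s = -1), "tau_s")
  expect_error(model_parameters(not_a_param = 3), "unknown")
  expect_error(model_parameters(g_baseline = 2000, g_reactivated = 100),
               "g_reactivated")
  expect_error(model_parameters(S_init = 1.5), "S_init")
})
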