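profile: mindchange-defaults-v1
time_unit: ms
parameters:
  a: 270.0
  b: 108.0
  d: 0.154
  gamma: 0.641
  tau_s: 100.0
  J_N_self: 0.2609
  J_N_cross: 0.0497
  I0: 0.3255
  J_A_ext: 0.00052
  mu0: 30.0
  decision_threshold: 35.5
  J_mc0: 0.0072
  tau_mc: 350.0
  J_V_inh: 0.1
  J_N_inh: 1.0
  mu_tonic: 7.0
  g_baseline: 1000.0
  g_reactivated: 3000.0
  tau_h: 300.0
  J_motor: 1.0
  J_N_LR: 2.0
  J_N_RL: 2.0
  T_pos: 750.0
  M_th: 17.4
  sigma_noise: 0.0125
  tau_noise: 12.0
  S_init: 0.1
protocol:
  t_stimulus_onset: 900.0
  t_timeout: 4000.0
  delay_inh: 400.0
  delay_unc: 500.0
  dt: 0.5
  epsilon_grid:
  - 0.0
  - 3.2
  - 6.4
  - 12.8
  - 25.6
  - 51.2
  n_trials: 8000.0
  master_seed: 1.0
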