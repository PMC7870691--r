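densities:
  rho0_elas: 0.35
  rho0_coll: 0.3
  rho0_csmc: 0.3
  rho0_ssmc: 0.05
passive:
  C10: 0.04
  k1: 1.0
  k2: 1.5
  kappa: 0.1
  alpha: 0.392699081698724
smc:
  mu_csmc: 0.42
  kappa_c: 1.55
prestretch:
  g_ax: 1.67
  g_coll: 1.1
damage:
  m_csmc: 1.0
  m_coll_dmg: 20.0
  m_ec: 0.38
remodeling:
  K_qh: 0.006931471805599
  K_m: 26.640000000000001
  K_pl: 4.0
  K_ec: 0.08
  K_dd: 1.6
  K_ic: 0.01
  dt_day: 1.0
  variant: original
contractility:
  k3: 0.4
  k4: 0.1
  k7: 0.01
  k2_hom: 0.5
  alpha2: 0.1
  K_CaCaM: 1.78e-07
  alpha_Ca: 0.24
  K_NO: 8.0e-08
  K_PE: 2.0e-07
  Ca_hom: 2.7e-07
  alpha_NO: 1.4e-07
  alpha_PE: 1.28e-07
  ACh_amp: 2.8e-07
  ACh_offset: 8.199999999999999
  ACh_shape: 0.9
  eta: 60.0
  dt_s: 0.01
geometry:
  inner_diameter: 0.65
  thickness: 0.04
  segment_length: 0.04
  pressure: 0.01
  n_theta: 48.0
  n_r: 3.0
  n_theta_lumen: 4001.0
myograph:
  rod_radius: 0.15
  preload_per_length: 0.0133
  dose_PE: 1.0e-06
  dose_ACh: 1.0e-05
  dose_NO: 1.0e-06
numerics:
  latch_tone_in_vivo: no
  g_elas_bracket:
  - 0.05
  - 2.5
  tol_equil: 1.0e-12
  prune_tol: 1.0e-08
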