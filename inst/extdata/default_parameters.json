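{
  "material_GPa": {
    "K": 17.84, "mu": 7.32, "alpha1": -2.87, "alpha2": -2.25,
    "mu1": -1.71, "mu2": -1.09, "beta1": 2.97, "beta2": 1.47, "beta3": 2.14
  },
  "second_gradient_N": { "Ks1": 1.5, "Ks2": 1.5, "Kb1": 1.5, "Kb2": 1.5 },
  "reorientation": { "c_gamma": 6.048e5, "tau_gamma": 1e-3 },
  "stiffness_evolution": {
    "c_mu": 6.048e12, "tau_mu": 1e4, "S0_mu": 3660,
    "c_beta1": 6.048e12, "tau_beta1": 1e4, "S0_beta1": 1484.8,
    "c_beta2": 6.048e12, "tau_beta2": 1e4, "S0_beta2": 734.29
  },
  "stimulus_diffusion": {
    "d_mu": 3.024e6, "kappa_mu": 1e-4, "R_mu": 35,
    "d_beta1": 6.048e6, "kappa_beta1": 1e-4, "R_beta1": 35,
    "d_beta2": 6.048e6, "kappa_beta2": 1e-4, "R_beta2": 35
  },
  "loading": {
    "geometry_m": [0.075, 0.025],
    "cantilever": { "tau0_N_per_m": 1.25e5, "Ts_s": 60480 },
    "three_point": { "u0_m": 2e-3, "span_m": 0.1375, "Ts_s": 60480 }
  }
}
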