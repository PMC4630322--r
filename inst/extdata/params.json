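{
  "params_version": "1.0",
  "hgb_molecular_weight": 64450,
  "hgb_blood_concentration_low": 122,
  "hgb_blood_concentration_high": 150,
  "large_vessel_hgb_molar": 0.002,
  "tissue_hematocrit_ratio": 0.8,
  "oxyphoric_power": 4,
  "blood_saturation": 0.75,
  "hill_coefficient": 2.73,
  "p50_mmHg": 26,
  "solubility_alpha": 0.00139,
  "hill_hgb": 0.0048,
  "oxygen_boundary": 0.00053,
  "glucose_boundary": 0.005,
  "waste_boundary": 0,
  "growth_factor_boundary": 0,
  "growth_inhibitor_boundary": 0,
  "diffusion_oxygen": 0.0594,
  "diffusion_glucose": 0.00152,
  "diffusion_waste": 0.002124,
  "diffusion_growth_factor": 1e-06,
  "diffusion_growth_inhibitor": 1e-06,
  "rate_proliferating_oxygen": 108,
  "rate_proliferating_glucose": 162,
  "rate_proliferating_waste": 240,
  "rate_proliferating_growth_factor": 1,
  "rate_proliferating_growth_inhibitor": 0,
  "rate_quiescent_oxygen": 50,
  "rate_quiescent_glucose": 80,
  "rate_quiescent_waste": 110,
  "rate_quiescent_growth_factor": 0.5,
  "rate_quiescent_growth_inhibitor": 1,
  "rate_necrotic_growth_inhibitor": 2,
  "oxygen_per_glucose_aerobic": 6,
  "atp_per_glucose_aerobic": 30,
  "atp_per_glucose_anaerobic": 2,
  "atp_per_waste": 3.5,
  "h_p": 828,
  "h_q": 393.4,
  "health_decay": 1,
  "necrosis_threshold": 0.5,
  "proliferation_threshold": 1.5,
  "r_mitosis": 0.0315,
  "sigma_mitosis": 0.01,
  "hayflick_limit": 60,
  "mutation_increment_prob": 0.05,
  "stem_spawn_period": 70,
  "dissolution_delay": 100,
  "cell_radius": 0.001,
  "k_pp": 1.0,
  "k_pq": 0.5,
  "k_qq": 0.25,
  "spring_cutoff": 1.2,
  "chemo_alpha": 1,
  "chemo_beta": 1,
  "chemo_gamma": 0.5,
  "mobility": 0.1,
  "uptake_coupling": 2e-05
}
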