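{
  "comment": "Default synthetic-cohort parameters. Group sizes echo the published per-protocol groups (259/53/12 PFH) plus an NFH stratum; all rates are placeholders, not estimates of the trial.",
  "n": {"multifaceted": 259, "unifaceted": 53, "pfh_control": 12, "nfh": 500},
  "p_symptomatic": {"multifaceted": 0.22, "unifaceted": 0.26, "pfh_control": 0.30, "nfh": 0.15},
  "p_ics_given_symptomatic": {"multifaceted": 0.35, "unifaceted": 0.35, "pfh_control": 0.40, "nfh": 0.25},
  "p_reversibility_pos": {
    "multifaceted": {"symptomatic": 0.25, "asymptomatic": 0.05},
    "unifaceted": {"symptomatic": 0.28, "asymptomatic": 0.06},
    "pfh_control": {"symptomatic": 0.30, "asymptomatic": 0.07},
    "nfh": {"symptomatic": 0.20, "asymptomatic": 0.03}
  },
  "p_hyperreactivity_pos": {
    "multifaceted": {"symptomatic": 0.30, "asymptomatic": 0.06},
    "unifaceted": {"symptomatic": 0.33, "asymptomatic": 0.07},
    "pfh_control": {"symptomatic": 0.35, "asymptomatic": 0.08},
    "nfh": {"symptomatic": 0.22, "asymptomatic": 0.04}
  },
  "resource_rates": {
    "multifaceted": {"gp_visit": 1.2, "specialist_visit": 0.3, "hospital_admission": 0.03, "chest_xray": 0.15, "ria_allergen_test": 0.4, "medication": 0.8, "nurse_visit": 4, "hdm_impermeable_cover": 3, "hypoallergenic_formula": 1, "brochure": 1},
    "unifaceted": {"gp_visit": 1.2, "specialist_visit": 0.3, "hospital_admission": 0.03, "chest_xray": 0.15, "ria_allergen_test": 0.4, "medication": 0.8, "nurse_visit": 2, "hdm_impermeable_cover": 1.5, "hypoallergenic_formula": 0.5, "brochure": 0.5},
    "pfh_control": {"gp_visit": 1.2, "specialist_visit": 0.3, "hospital_admission": 0.03, "chest_xray": 0.15, "ria_allergen_test": 0.4, "medication": 0.8},
    "nfh": {"gp_visit": 1.0, "specialist_visit": 0.2, "hospital_admission": 0.02, "chest_xray": 0.1, "ria_allergen_test": 0.3, "medication": 0.6}
  },
  "missingness": {"symptomatic": 0.05, "reversibility": 0.1, "hyperreactivity": 0.1},
  "seed": 20090101
}
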