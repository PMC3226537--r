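{
  "comment": "Placeholder unit prices (EUR). The actual standardised Dutch unit prices used in the trial are not published; these round values only make the pipeline runnable and are clearly NOT 2009 Dutch tariffs.",
  "target_year": 2009,
  "index_factors": {"2007": 1.05, "2008": 1.02, "2009": 1.0},
  "items": [
    {"item": "gp_visit", "unit_price": 28.0, "price_year": 2009, "category": "direct_medical"},
    {"item": "specialist_visit", "unit_price": 72.0, "price_year": 2009, "category": "direct_medical"},
    {"item": "hospital_admission", "unit_price": 400.0, "price_year": 2009, "category": "direct_medical"},
    {"item": "chest_xray", "unit_price": 45.0, "price_year": 2009, "category": "direct_medical"},
    {"item": "ria_allergen_test", "unit_price": 40.0, "price_year": 2009, "category": "direct_medical"},
    {"item": "medication", "unit_price": 30.0, "price_year": 2009, "category": "direct_medical"},
    {"item": "nurse_visit", "unit_price": 35.0, "price_year": 2009, "category": "intervention"},
    {"item": "hdm_impermeable_cover", "unit_price": 60.0, "price_year": 2009, "category": "intervention"},
    {"item": "hypoallergenic_formula", "unit_price": 150.0, "price_year": 2009, "category": "intervention"},
    {"item": "brochure", "unit_price": 5.0, "price_year": 2009, "category": "intervention"}
  ]
}
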