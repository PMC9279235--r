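{
  "model": "brock_full_with_spiculation",
  "version": "1.0",
  "source": "McWilliams A, Tammemagi MC, Mayo JR, et al. Probability of cancer in pulmonary nodules detected on first screening CT. N Engl J Med. 2013;368(10):910-919. Full model (model 2b) with spiculation.",
  "intercept": -6.7892,
  "terms": {
    "age": {"coefficient": 0.0287, "center": 62, "note": "per year, centred at 62"},
    "sex": {"coefficient": 0.6011, "note": "indicator, female = 1"},
    "family_history": {"coefficient": 0.2961, "note": "indicator"},
    "emphysema": {"coefficient": 0.2953, "note": "indicator"},
    "size": {"coefficient": -5.3854, "transform": "inverse_sqrt_cm", "center": 1.58113883,
             "note": "coefficient applies to (diameter_mm/10)^(-1/2) - 1.58113883; the centring constant is (4/10)^(-1/2), i.e. a 4 mm reference nodule"},
    "upper_lobe": {"coefficient": 0.6581, "note": "indicator"},
    "part_solid": {"coefficient": 0.3776, "note": "indicator, nodule type part-solid"},
    "nodule_count": {"coefficient": -0.0824, "center": 4, "note": "per nodule, centred at 4"},
    "spiculation": {"coefficient": 0.7729, "note": "indicator"}
  }
}
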