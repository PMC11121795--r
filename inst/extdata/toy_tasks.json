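[
  {"id": "T_PRECURSOR",
   "description": "biomass precursor synthesis from glucose, ammonium and phosphate",
   "substrates": {"glc_c": 10, "nh4_c": 10, "pi_c": 10},
   "products": {"prec_c": 0}},
  {"id": "T_RESPIRATION",
   "description": "oxidative CO2 production under the model's own exchange bounds",
   "substrates": {},
   "products": {"co2_c": 0}},
  {"id": "T_O2_CAPACITY",
   "description": "oxygen supply capacity under the model's exchange bounds",
   "substrates": {},
   "products": {"o2_c": 0}},
  {"id": "T_AMINO_UPTAKE",
   "description": "amino acid supply relying on the exchange bounds only",
   "substrates": {},
   "products": {"aa_c": 0}},
  {"id": "T_AA_SECRETION",
   "description": "spare amino acid export capacity",
   "substrates": {"glc_c": 5, "nh4_c": 5},
   "products": {"aa_e": 0}},
  {"id": "T_GLYC_OVERFLOW",
   "description": "lactate overflow under the model's own glucose exchange bounds",
   "substrates": {},
   "products": {"lac_c": 0}},
  {"id": "T_LAC_EXPORT",
   "description": "spare lactate export capacity beyond the forced secretion",
   "substrates": {},
   "products": {"lac_e": 0}},
  {"id": "T_HIGH_DEMAND",
   "description": "unreachable precursor demand (expected infeasible)",
   "substrates": {"glc_c": 10},
   "products": {"prec_c": 1000}}
]
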