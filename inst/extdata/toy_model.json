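{
  "id": "toy_ec22",
  "name": "22-reaction toy endothelial-style network (synthetic fixture)",
  "metabolites": [
    {"id": "glc_e", "name": "glucose (extracellular)", "compartment": "e"},
    {"id": "glc_c", "name": "glucose", "compartment": "c"},
    {"id": "o2_e", "name": "oxygen (extracellular)", "compartment": "e"},
    {"id": "o2_c", "name": "oxygen", "compartment": "c"},
    {"id": "nh4_e", "name": "ammonium (extracellular)", "compartment": "e"},
    {"id": "nh4_c", "name": "ammonium", "compartment": "c"},
    {"id": "pi_e", "name": "phosphate (extracellular)", "compartment": "e"},
    {"id": "pi_c", "name": "phosphate", "compartment": "c"},
    {"id": "aa_e", "name": "amino acid pool (extracellular)", "compartment": "e"},
    {"id": "aa_c", "name": "amino acid pool", "compartment": "c"},
    {"id": "pyr_c", "name": "pyruvate", "compartment": "c"},
    {"id": "lac_c", "name": "lactate", "compartment": "c"},
    {"id": "lac_e", "name": "lactate (extracellular)", "compartment": "e"},
    {"id": "co2_c", "name": "carbon dioxide", "compartment": "c"},
    {"id": "co2_e", "name": "carbon dioxide (extracellular)", "compartment": "e"},
    {"id": "atp_c", "name": "ATP equivalent", "compartment": "c"},
    {"id": "prec_c", "name": "biomass precursor", "compartment": "c"},
    {"id": "dead_c", "name": "dead-end metabolite", "compartment": "c"},
    {"id": "x_e", "name": "unused boundary metabolite", "compartment": "e"}
  ],
  "reactions": [
    {"id": "EX_glc", "name": "glucose exchange", "metabolites": {"glc_e": -1},
     "lower_bound": -10, "upper_bound": 0, "gene_reaction_rule": ""},
    {"id": "EX_o2", "name": "oxygen exchange", "metabolites": {"o2_e": -1},
     "lower_bound": -20, "upper_bound": 0, "gene_reaction_rule": ""},
    {"id": "EX_nh4", "name": "ammonium exchange", "metabolites": {"nh4_e": -1},
     "lower_bound": -10, "upper_bound": 10, "gene_reaction_rule": ""},
    {"id": "EX_pi", "name": "phosphate exchange", "metabolites": {"pi_e": -1},
     "lower_bound": -10, "upper_bound": 0, "gene_reaction_rule": ""},
    {"id": "EX_aa", "name": "amino acid exchange", "metabolites": {"aa_e": -1},
     "lower_bound": -5, "upper_bound": 5, "gene_reaction_rule": ""},
    {"id": "EX_lac", "name": "lactate exchange", "metabolites": {"lac_e": -1},
     "lower_bound": 0, "upper_bound": 20, "gene_reaction_rule": ""},
    {"id": "EX_co2", "name": "carbon dioxide exchange", "metabolites": {"co2_e": -1},
     "lower_bound": 0, "upper_bound": 40, "gene_reaction_rule": ""},
    {"id": "EX_x", "name": "blocked exchange", "metabolites": {"x_e": -1},
     "lower_bound": -10, "upper_bound": 10, "gene_reaction_rule": ""},
    {"id": "GLCt", "name": "glucose transport", "metabolites": {"glc_e": -1, "glc_c": 1},
     "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": "g_glct"},
    {"id": "O2t", "name": "oxygen transport", "metabolites": {"o2_e": -1, "o2_c": 1},
     "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": "g_o2t"},
    {"id": "NH4t", "name": "ammonium transport", "metabolites": {"nh4_e": -1, "nh4_c": 1},
     "lower_bound": -1000, "upper_bound": 1000, "gene_reaction_rule": "g_nh4t"},
    {"id": "PIt", "name": "phosphate transport", "metabolites": {"pi_e": -1, "pi_c": 1},
     "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": "g_pit"},
    {"id": "AAt", "name": "amino acid transport", "metabolites": {"aa_e": -1, "aa_c": 1},
     "lower_bound": -1000, "upper_bound": 1000, "gene_reaction_rule": "g_aat1 or g_aat2"},
    {"id": "GLYC", "name": "lumped glycolysis",
     "metabolites": {"glc_c": -1, "pyr_c": 2, "atp_c": 2},
     "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": "g_glyc1 and g_glyc2"},
    {"id": "RESP", "name": "lumped respiration",
     "metabolites": {"pyr_c": -1, "o2_c": -1, "co2_c": 1, "atp_c": 4},
     "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": "g_resp"},
    {"id": "FERM", "name": "lumped fermentation",
     "metabolites": {"pyr_c": -1, "lac_c": 1, "atp_c": 1},
     "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": "g_ferm"},
    {"id": "LACt", "name": "lactate export", "metabolites": {"lac_c": -1, "lac_e": 1},
     "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": ""},
    {"id": "CO2t", "name": "carbon dioxide export", "metabolites": {"co2_c": -1, "co2_e": 1},
     "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": ""},
    {"id": "AASYN", "name": "amino acid synthesis",
     "metabolites": {"pyr_c": -1, "nh4_c": -1, "atp_c": -1, "aa_c": 1},
     "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": "g_aasyn"},
    {"id": "PRECSYN", "name": "biomass precursor synthesis",
     "metabolites": {"pyr_c": -1, "aa_c": -1, "pi_c": -1, "atp_c": -1, "prec_c": 1},
     "lower_bound": 0, "upper_bound": 1000,
     "gene_reaction_rule": "g_prec1 and (g_prec2 or g_prec3)"},
    {"id": "BIOMASS", "name": "biomass drain",
     "metabolites": {"prec_c": -1, "aa_c": -1, "atp_c": -2},
     "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": "",
     "objective_coefficient": 1},
    {"id": "DEADEND", "name": "dead-end branch", "metabolites": {"glc_c": -1, "dead_c": 1},
     "lower_bound": 0, "upper_bound": 1000, "gene_reaction_rule": "g_dead"}
  ]
}
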