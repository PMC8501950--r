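{
  "_comment": "Per-phase true channel means (arbitrary units, above background) for the synthetic population, and genotoxin presets as per-phase multiplicative (mult) and additive (add) modifiers. Magnitudes are qualitative emulations of the published figure directions, not measured values: DarT WT limits EdU incorporation in S phase and induces gammaH2AX/RPA2 phosphorylation confined to replicating (PCNA-positive) cells; the catalytic mutant E160A is inert; HU ablates EdU incorporation; MMS elevates ADP-ribose signal indiscriminately of cell-cycle stage.",
  "base_means": {
    "EdU":   {"G1": 10,  "S": 300, "G2": 10},
    "PCNA":  {"G1": 15,  "S": 250, "G2": 15},
    "gH2AX": {"G1": 20,  "S": 20,  "G2": 20},
    "RPA2":  {"G1": 20,  "S": 20,  "G2": 20},
    "ADPr":  {"G1": 20,  "S": 20,  "G2": 20},
    "GFP":   {"G1": 50,  "S": 50,  "G2": 50}
  },
  "presets": {
    "untreated": {},
    "dart_e160a": {},
    "dart_wt": {
      "EdU":   {"S": {"mult": 0.3}},
      "gH2AX": {"S": {"add": 100}},
      "RPA2":  {"S": {"mult": 4}},
      "ADPr":  {"S": {"mult": 5}}
    },
    "hu": {
      "EdU":   {"S": {"mult": 0.02}},
      "gH2AX": {"S": {"add": 40}},
      "RPA2":  {"S": {"mult": 3}}
    },
    "cpt": {
      "gH2AX": {"S": {"add": 60}},
      "RPA2":  {"S": {"mult": 2.5}}
    },
    "mms": {
      "EdU":  {"S": {"mult": 0.5}},
      "ADPr": {"G1": {"mult": 6}, "S": {"mult": 6}, "G2": {"mult": 6}}
    }
  }
}
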