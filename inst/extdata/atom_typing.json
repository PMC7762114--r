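{
  "comment": "Editable interaction-typing tables. residue_kind maps residue names to molecule kinds (protein residues are additionally recognised by the standard 3-letter codes). acceptor_n / nonacceptor_o are 'RESNAME ATOMNAME' keys. hydrophobic maps residue name (or '*') to a regex over carbon atom names. charge lists one representative atom per charged group.",
  "residue_kind": {
    "lipid": ["DPP", "DPPC", "POP", "POPE", "LIP"],
    "water": ["HOH", "WAT", "TIP3", "SOL", "TIP"],
    "ion": ["NA", "K", "CL", "SOD", "POT", "CLA"],
    "protein": []
  },
  "acceptor_n": [],
  "nonacceptor_o": [],
  "hydrophobic": {
    "DPP": "^C(2([2-9]|1[0-6])|3([2-9]|1[0-6]))$",
    "DPPC": "^C(2([2-9]|1[0-6])|3([2-9]|1[0-6]))$",
    "POP": "^C(2([2-9]|1[0-8])|3([2-9]|1[0-6]))$",
    "POPE": "^C(2([2-9]|1[0-8])|3([2-9]|1[0-6]))$",
    "LIP": "^C(2([2-9]|1[0-9])|3([2-9]|1[0-9]))$",
    "PHE": "^(CB|CG|CD1|CD2|CE1|CE2|CZ)$",
    "TRP": "^(CB|CG|CD1|CD2|CE2|CE3|CZ2|CZ3|CH2)$",
    "LEU": "^(CB|CG|CD1|CD2)$",
    "ILE": "^(CB|CG1|CG2|CD1)$",
    "VAL": "^(CB|CG1|CG2)$",
    "MET": "^(CB|CG|CE)$",
    "PRO": "^(CB|CG|CD)$",
    "ALA": "^CB$",
    "LYS": "^(CB|CG|CD)$",
    "THR": "^CG2$",
    "TYR": "^(CB|CG|CD1|CD2|CE1|CE2)$"
  },
  "charge": [
    { "resname": "LYS", "atoms": ["NZ"], "charge": 1 },
    { "resname": "ARG", "atoms": ["NH1"], "charge": 1 },
    { "resname": "ASP", "atoms": ["OD2"], "charge": -1 },
    { "resname": "GLU", "atoms": ["OE2"], "charge": -1 },
    { "resname": "DPP", "atoms": ["P"], "charge": -1 },
    { "resname": "DPP", "atoms": ["N"], "charge": 1 },
    { "resname": "DPPC", "atoms": ["P"], "charge": -1 },
    { "resname": "DPPC", "atoms": ["N"], "charge": 1 },
    { "resname": "POP", "atoms": ["P"], "charge": -1 },
    { "resname": "POP", "atoms": ["N"], "charge": 1 },
    { "resname": "POPE", "atoms": ["P"], "charge": -1 },
    { "resname": "POPE", "atoms": ["N"], "charge": 1 },
    { "resname": "LIP", "atoms": ["P"], "charge": -1 },
    { "resname": "LIP", "atoms": ["N"], "charge": 1 },
    { "resname": "NA", "atoms": ["NA"], "charge": 1 },
    { "resname": "SOD", "atoms": ["SOD"], "charge": 1 },
    { "resname": "K", "atoms": ["K"], "charge": 1 },
    { "resname": "POT", "atoms": ["POT"], "charge": 1 },
    { "resname": "CL", "atoms": ["CL"], "charge": -1 },
    { "resname": "CLA", "atoms": ["CLA"], "charge": -1 }
  ]
}
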