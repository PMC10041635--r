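{
  "comment": "Structural taxonomy of boronic acids and the mechanistic pathways active for each class. Z denotes a basic ring nitrogen (pyridine-type, lone pair available: not pyrrole-type, not amide); X denotes a ring S or O. A declared category column always overrides SMILES classification; this file is a convenience encoding and may be replaced via --rules. SMARTS rules are evaluated top to bottom, most specific first; the first rule whose conditions all hold wins.",
  "heavy_atom_warning": 15,
  "boronic_acid_smarts": "[$([BX3]([OX2H])([OX2H])[#6])]",
  "categories": {
    "aryl": ["k2Ar"],
    "activated_aryl": ["k2Ar", "k2cat"],
    "basic_six_membered_heterocycle": ["k1", "k2", "k4"],
    "other_basic_heterocycle": ["k1", "k2", "k3", "k4"],
    "nonbasic_five_membered_heterocycle": ["k2", "k5"],
    "alkenyl": ["k1", "k2"]
  },
  "smarts_rules": [
    {
      "category": "other_basic_heterocycle",
      "all_of": ["[$([cr5][BX3]([OX2H])[OX2H])]", "[nX2r5]"],
      "note": "boron on a five-membered heteroaromatic ring carrying a basic (Z) nitrogen, e.g. azoles such as isoxazolyl boronic acids"
    },
    {
      "category": "basic_six_membered_heterocycle",
      "all_of": ["[$([cr6][BX3]([OX2H])[OX2H])]", "[nX2r6]"],
      "note": "boron on a six-membered azine ring (pyridine-type Z nitrogen); zwitterion pathway k4 available"
    },
    {
      "category": "nonbasic_five_membered_heterocycle",
      "all_of": ["[$([cr5][BX3]([OX2H])[OX2H])]"],
      "any_of": ["[or5]", "[sr5]"],
      "none_of": ["[nX2]"],
      "note": "boron on a five-membered heteroaromatic with X = S or O and no basic nitrogen (furanyl/thienyl)"
    },
    {
      "category": "activated_aryl",
      "all_of": ["[$(c[BX3]([OX2H])[OX2H])]"],
      "min_counts": {"c[F,Cl,Br,I]": 3},
      "note": "strongly electron-poor (polyhalogenated) aryl boronic acids; fast protodeboronation with the self-coupled k2cat pathway in addition to k2Ar"
    },
    {
      "category": "aryl",
      "all_of": ["[$(c[BX3]([OX2H])[OX2H])]"],
      "note": "simple aryl (carbocyclic aromatic) boronic acids"
    },
    {
      "category": "alkenyl",
      "all_of": ["[$([CX3]([BX3]([OX2H])[OX2H])=[CX3])]"],
      "note": "vinyl/alkenyl boronic acids"
    }
  ]
}
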