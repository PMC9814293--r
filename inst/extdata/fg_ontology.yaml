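# Functional-group ontology for on-DNA library design.
#
# Each entry defines one FG: a reactive handle (or a protected precursor of
# one) recognisable by a SMARTS pattern.  `parent` encodes the annotation
# hierarchy: a child pattern must match a subset of the sites its parent
# matches, so that per-site leaf resolution can be done by match-count
# arithmetic.  `class_tags` drive pairwise FG incompatibility expansion
# (strong electrophiles / strong nucleophiles are mutually incompatible
# within and across classes).  id 0 is reserved for the null FG and is
# added by the loader.
fgs:
  - {id: 1,  name: amine,                     smarts: "[NX3;H2,H1;!$([N][!#6]);!$([N]C=[O,S,N]);!$([N]S=O);!$([N]C#N)]",
     parent: ~, protected: false, class_tags: [strong_nucleophile]}
  - {id: 2,  name: amine_aliphatic,           smarts: "[NX3;H2,H1;!$([N][!#6]);!$([N]c);!$([N]C=[O,S,N]);!$([N]S=O);!$([N]C#N)]",
     parent: amine, protected: false, class_tags: [strong_nucleophile]}
  - {id: 3,  name: amine_aliphatic_primary,   smarts: "[NX3;H2;$([N][CX4]);!$([N]C=[O,S,N]);!$([N]S=O)]",
     parent: amine_aliphatic, protected: false, class_tags: [strong_nucleophile]}
  - {id: 4,  name: amine_aliphatic_secondary, smarts: "[NX3;H1;$([N]([CX4])[CX4])]",
     parent: amine_aliphatic, protected: false, class_tags: [strong_nucleophile]}
  - {id: 5,  name: amine_aromatic,            smarts: "[NX3;H2;$([N][c])]",
     parent: amine, protected: false, class_tags: [strong_nucleophile]}
  - {id: 6,  name: carboxylic_acid,           smarts: "[CX3](=O)[OX2H1]",
     parent: ~, protected: false, class_tags: []}
  - {id: 7,  name: aldehyde,                  smarts: "[CX3H1](=O)[#6]",
     parent: ~, protected: false, class_tags: []}
  - {id: 8,  name: ketone,                    smarts: "[#6][CX3](=O)[#6]",
     parent: ~, protected: false, class_tags: []}
  - {id: 9,  name: phenol,                    smarts: "[OX2H][c]",
     parent: ~, protected: false, class_tags: []}
  - {id: 10, name: thiol,                     smarts: "[SX2H]",
     parent: ~, protected: false, class_tags: [strong_nucleophile]}
  - {id: 11, name: azide,                     smarts: "[#6][NX2]=[NX2+]=[NX1-]",
     parent: ~, protected: false, class_tags: []}
  - {id: 12, name: alkyne_terminal,           smarts: "[CX2H1]#[CX2][#6]",
     parent: ~, protected: false, class_tags: []}
  - {id: 13, name: aryl_halide,               smarts: "[c][Br,I]",
     parent: ~, protected: false, class_tags: []}
  - {id: 14, name: boronate,                  smarts: "[c][BX3]([OX2H])[OX2H]",
     parent: ~, protected: false, class_tags: []}
  - {id: 15, name: sulfonyl_chloride,         smarts: "[SX4](=O)(=O)[Cl]",
     parent: ~, protected: false, class_tags: [strong_electrophile]}
  - {id: 16, name: isocyanate,                smarts: "[NX2]=[CX2]=[OX1]",
     parent: ~, protected: false, class_tags: [strong_electrophile]}
  - {id: 17, name: boc_amine,                 smarts: "[NX3;H1]([CX4])C(=O)O[CX4]([CH3])([CH3])[CH3]",
     parent: ~, protected: true, class_tags: []}
  - {id: 18, name: fmoc_amine,                smarts: "[NX3;H1]([CX4])C(=O)OCC1c2ccccc2-c2ccccc21",
     parent: ~, protected: true, class_tags: []}
  - {id: 19, name: nitro_aromatic,            smarts: "[c][N+](=O)[O-]",
     parent: ~, protected: true, class_tags: []}
  - {id: 20, name: fluoronitroarene_ortho,    smarts: "[F][cX3]:[cX3][N+](=O)[O-]",
     parent: nitro_aromatic, protected: false, class_tags: [strong_electrophile]}
  - {id: 21, name: dichlorotriazine,          smarts: "[Cl][c]1[n][c]([Cl])[n][c][n]1",
     parent: ~, protected: false, class_tags: [strong_electrophile]}
  - {id: 22, name: monochlorotriazine,        smarts: "[Cl][c]1[n][c]([NX3,OX2,SX2])[n][c]([NX3,OX2,SX2])[n]1",
     parent: ~, protected: false, class_tags: [strong_electrophile]}
  - {id: 23, name: ester,                     smarts: "[#6][CX3](=O)[OX2][CX4]",
     parent: ~, protected: false, class_tags: []}
  - {id: 24, name: acyl_chloride,             smarts: "[CX3](=O)[Cl]",
     parent: ~, protected: false, class_tags: [strong_electrophile]}
  # design-side intermediate produced by SNAr on an ortho-fluoronitroarene;
  # the aryl N-H and the ortho nitro together enable benzimidazole closure
  - {id: 25, name: nitroarylamine,            smarts: "[NX3;H1]([CX4])[c]:[c][N+](=O)[O-]",
     parent: ~, protected: false, class_tags: []}

# Pairwise incompatibilities in addition to the class-tag expansion.
# Aldehydes are kept out of amine-bearing building blocks (imine instability).
extra_incompatible_pairs:
  - [aldehyde, amine]
  - [aldehyde, amine_aliphatic]
  - [aldehyde, amine_aliphatic_primary]
  - [aldehyde, amine_aliphatic_secondary]
  - [aldehyde, amine_aromatic]

# FGs that may not remain live on a finished design.
disallowed_final_fgs: [sulfonyl_chloride, isocyanate, dichlorotriazine,
                       fluoronitroarene_ortho, acyl_chloride]

# FGs whose presence disqualifies a building block outright.
unwanted_fgs: [acyl_chloride]
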