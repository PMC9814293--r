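# Default on-DNA reaction set.
#
# Connecting reactions consume (design_fg, bb_fg); deprotections consume a
# single design FG.  `transform` is a reaction SMARTS executed by the
# structure-rewrite backend during enumeration; the design (or the lone
# reactant of a deprotection) is always the first component.  Atom deltas
# state the heavy atoms gained (+) or lost (-) by each side when the
# reaction runs; `scaffold_atoms` counts atoms brought in by a scaffold-
# adding deprotection.  Reactions sharing an `enum_index` can be pooled in
# one experimental step (e.g. amidation of primary and secondary amines).
reactions:
  - {rxn_id: amide_acid_on_design_prim, kind: connecting,
     inputs: [carboxylic_acid, amine_aliphatic_primary], outputs: [],
     enum_index: 1, design_side_atom_delta: -1, bb_side_atom_delta: 0, scaffold_atoms: 0,
     transform: "[C:1](=[O:2])[OX2H1].[NX3;H2:3]>>[C:1](=[O:2])[N:3]",
     production_status: production}
  - {rxn_id: amide_acid_on_design_sec, kind: connecting,
     inputs: [carboxylic_acid, amine_aliphatic_secondary], outputs: [],
     enum_index: 1, design_side_atom_delta: -1, bb_side_atom_delta: 0, scaffold_atoms: 0,
     transform: "[C:1](=[O:2])[OX2H1].[NX3;H1:3]([CX4:4])[CX4:5]>>[C:1](=[O:2])[N:3]([C:4])[C:5]",
     production_status: production}
  - {rxn_id: amide_acid_on_design_anil, kind: connecting,
     inputs: [carboxylic_acid, amine_aromatic], outputs: [],
     enum_index: 1, design_side_atom_delta: -1, bb_side_atom_delta: 0, scaffold_atoms: 0,
     transform: "[C:1](=[O:2])[OX2H1].[NX3;H2:3][c:4]>>[C:1](=[O:2])[N:3][c:4]",
     production_status: validated}
  - {rxn_id: amide_amine_on_design_prim, kind: connecting,
     inputs: [amine_aliphatic_primary, carboxylic_acid], outputs: [],
     enum_index: 2, design_side_atom_delta: 0, bb_side_atom_delta: -1, scaffold_atoms: 0,
     transform: "[NX3;H2:1].[C:2](=[O:3])[OX2H1]>>[N:1][C:2]=[O:3]",
     production_status: production}
  - {rxn_id: amide_amine_on_design_sec, kind: connecting,
     inputs: [amine_aliphatic_secondary, carboxylic_acid], outputs: [],
     enum_index: 2, design_side_atom_delta: 0, bb_side_atom_delta: -1, scaffold_atoms: 0,
     transform: "[NX3;H1:1]([CX4:4])[CX4:5].[C:2](=[O:3])[OX2H1]>>[C:4][N:1]([C:5])[C:2]=[O:3]",
     production_status: production}
  - {rxn_id: reductive_amination_ald_on_design, kind: connecting,
     inputs: [aldehyde, amine_aliphatic_primary], outputs: [amine_aliphatic_secondary],
     enum_index: 3, design_side_atom_delta: -1, bb_side_atom_delta: 0, scaffold_atoms: 0,
     transform: "[CX3;H1:1]=[OX1].[NX3;H2:2]>>[CX4;H2:1][NX3;H1:2]",
     production_status: production}
  - {rxn_id: reductive_amination_amine_on_design, kind: connecting,
     inputs: [amine_aliphatic_primary, aldehyde], outputs: [amine_aliphatic_secondary],
     enum_index: 4, design_side_atom_delta: 0, bb_side_atom_delta: -1, scaffold_atoms: 0,
     transform: "[NX3;H2:1].[CX3;H1:2]=[OX1]>>[NX3;H1:1][CX4;H2:2]",
     production_status: production}
  - {rxn_id: snar_fnar_on_design_amine, kind: connecting,
     inputs: [fluoronitroarene_ortho, amine_aliphatic_primary], outputs: [nitroarylamine],
     enum_index: 5, design_side_atom_delta: -1, bb_side_atom_delta: 0, scaffold_atoms: 0,
     transform: "[F][c:1]:[c:2][N+:3](=[O:4])[O-:5].[NX3;H2:6]>>[N:6][c:1]:[c:2][N+:3](=[O:4])[O-:5]",
     production_status: production}
  - {rxn_id: snar_amine_on_design_fnar, kind: connecting,
     inputs: [amine_aliphatic_primary, fluoronitroarene_ortho], outputs: [nitroarylamine],
     enum_index: 6, design_side_atom_delta: 0, bb_side_atom_delta: -1, scaffold_atoms: 0,
     transform: "[NX3;H2:1].[F][c:2]:[c:3][N+:4](=[O:5])[O-:6]>>[N:1][c:2]:[c:3][N+:4](=[O:5])[O-:6]",
     production_status: production}
  - {rxn_id: benzimidazole_nitro_on_design, kind: connecting,
     inputs: [nitroarylamine, aldehyde], outputs: [],
     enum_index: 7, design_side_atom_delta: -2, bb_side_atom_delta: -1, scaffold_atoms: 0,
     transform: "[NX3;H1:1][c:2]:[c:3][N+](=[O])[O-].[CX3;H1:5]=[OX1]>>[N:1]1[c:2]:[c:3][N]=[C:5]1",
     production_status: production}
  - {rxn_id: snar_triazine_amine, kind: connecting,
     inputs: [dichlorotriazine, amine_aliphatic_primary], outputs: [monochlorotriazine],
     enum_index: 8, design_side_atom_delta: -1, bb_side_atom_delta: 0, scaffold_atoms: 0,
     transform: "[Cl][c:1]([n:2])[n:3].[NX3;H2:4]>>[N:4][c:1]([n:2])[n:3]",
     production_status: production}
  - {rxn_id: snar_triazine_phenol, kind: connecting,
     inputs: [dichlorotriazine, phenol], outputs: [monochlorotriazine],
     enum_index: 9, design_side_atom_delta: -1, bb_side_atom_delta: 0, scaffold_atoms: 0,
     transform: "[Cl][c:1]([n:2])[n:3].[OX2;H1:4][c:5]>>[c:5][O:4][c:1]([n:2])[n:3]",
     production_status: production}
  - {rxn_id: snar_monotriazine_amine, kind: connecting,
     inputs: [monochlorotriazine, amine_aliphatic_primary], outputs: [],
     enum_index: 10, design_side_atom_delta: -1, bb_side_atom_delta: 0, scaffold_atoms: 0,
     transform: "[Cl][c:1]([n:2])[n:3].[NX3;H2:4]>>[N:4][c:1]([n:2])[n:3]",
     production_status: production}
  - {rxn_id: sulfonamide_amine_on_design, kind: connecting,
     inputs: [amine_aliphatic_primary, sulfonyl_chloride], outputs: [],
     enum_index: 11, design_side_atom_delta: 0, bb_side_atom_delta: -1, scaffold_atoms: 0,
     transform: "[NX3;H2:1].[SX4:2](=[O:3])(=[O:4])[Cl]>>[N:1][S:2](=[O:3])=[O:4]",
     production_status: production}
  - {rxn_id: urea_amine_on_design, kind: connecting,
     inputs: [amine_aliphatic_primary, isocyanate], outputs: [],
     enum_index: 12, design_side_atom_delta: 0, bb_side_atom_delta: 0, scaffold_atoms: 0,
     transform: "[NX3;H2:1].[NX2:2]=[CX2:3]=[OX1:4]>>[N:1][C:3](=[O:4])[N:2]",
     production_status: validated}
  - {rxn_id: suzuki_halide_on_design, kind: connecting,
     inputs: [aryl_halide, boronate], outputs: [],
     enum_index: 13, design_side_atom_delta: -1, bb_side_atom_delta: -3, scaffold_atoms: 0,
     transform: "[c:1][Br,I].[c:2][BX3]([OX2H])[OX2H]>>[c:1][c:2]",
     production_status: validated}
  - {rxn_id: click_azide_on_design, kind: connecting,
     inputs: [azide, alkyne_terminal], outputs: [],
     enum_index: 14, design_side_atom_delta: 0, bb_side_atom_delta: 0, scaffold_atoms: 0,
     transform: "[#6:1][NX2:2]=[NX2+:3]=[NX1-:4].[CX2;H1:5]#[CX2:6]>>[#6:1][N:2]1[N;+0:3]=[N;+0:4][C:6]=[C:5]1",
     production_status: validated}
  - {rxn_id: boc_removal, kind: deprotection,
     inputs: [boc_amine], outputs: [amine_aliphatic_primary],
     enum_index: 101, design_side_atom_delta: -7, bb_side_atom_delta: 0, scaffold_atoms: 0,
     transform: "[NX3;H1:1]C(=O)O[CX4]([CH3])([CH3])[CH3]>>[NX3;H2:1]",
     production_status: production}
  - {rxn_id: fmoc_removal, kind: deprotection,
     inputs: [fmoc_amine], outputs: [amine_aliphatic_primary],
     enum_index: 102, design_side_atom_delta: -17, bb_side_atom_delta: 0, scaffold_atoms: 0,
     transform: "[NX3;H1:1]C(=O)OCC1c2ccccc2-c2ccccc21>>[NX3;H2:1]",
     production_status: production}
  - {rxn_id: triazine_scaffold, kind: deprotection,
     inputs: [amine_aliphatic_primary], outputs: [dichlorotriazine],
     enum_index: 103, design_side_atom_delta: 0, bb_side_atom_delta: 0, scaffold_atoms: 8,
     transform: "[NX3;H2:1]>>[NX3;H1:1][c]1[n][c]([Cl])[n][c]([Cl])[n]1",
     production_status: production}
  - {rxn_id: nitro_reduction, kind: deprotection,
     inputs: [nitro_aromatic], outputs: [amine_aromatic],
     enum_index: 104, design_side_atom_delta: -2, bb_side_atom_delta: 0, scaffold_atoms: 0,
     transform: "[c:1][NX3+](=[OX1])[OX1-]>>[c:1][NX3;H2]",
     production_status: validated}
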