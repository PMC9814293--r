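# Reaction x FG incompatibilities. context = on_dna: the FG may not be live
# on the growing design (beyond the instance the reaction consumes) when the
# reaction runs; off_dna: the FG may not ride in on the incoming building
# block (beyond the consumed instance). Rules encode selectivity clashes:
# a second copy of the consumed handle, or a competing nucleophile under the
# same conditions, would react ambiguously.
rxn_id,fg_name,context
amide_acid_on_design_prim,carboxylic_acid,on_dna
amide_acid_on_design_sec,carboxylic_acid,on_dna
amide_acid_on_design_anil,carboxylic_acid,on_dna
amide_amine_on_design_prim,amine_aliphatic_primary,on_dna
amide_amine_on_design_prim,amine_aliphatic_secondary,on_dna
amide_amine_on_design_sec,amine_aliphatic_primary,on_dna
amide_amine_on_design_sec,amine_aliphatic_secondary,on_dna
reductive_amination_ald_on_design,aldehyde,on_dna
reductive_amination_amine_on_design,amine_aliphatic_primary,on_dna
reductive_amination_amine_on_design,amine_aliphatic_secondary,on_dna
snar_fnar_on_design_amine,fluoronitroarene_ortho,on_dna
snar_fnar_on_design_amine,thiol,off_dna
snar_amine_on_design_fnar,amine_aliphatic_primary,on_dna
snar_amine_on_design_fnar,amine_aliphatic_secondary,on_dna
snar_triazine_amine,amine_aliphatic_primary,on_dna
snar_triazine_amine,phenol,off_dna
snar_triazine_amine,thiol,off_dna
snar_triazine_phenol,phenol,on_dna
snar_triazine_phenol,amine_aliphatic_primary,off_dna
snar_triazine_phenol,thiol,off_dna
snar_monotriazine_amine,amine_aliphatic_primary,on_dna
snar_monotriazine_amine,phenol,off_dna
snar_monotriazine_amine,thiol,off_dna
sulfonamide_amine_on_design,amine_aliphatic_primary,on_dna
sulfonamide_amine_on_design,amine_aliphatic_secondary,on_dna
sulfonamide_amine_on_design,phenol,on_dna
urea_amine_on_design,amine_aliphatic_primary,on_dna
urea_amine_on_design,amine_aliphatic_secondary,on_dna
triazine_scaffold,amine_aliphatic_primary,on_dna
triazine_scaffold,amine_aliphatic_secondary,on_dna
triazine_scaffold,amine_aromatic,on_dna
boc_removal,fmoc_amine,on_dna
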