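# pepiso rule table for pKa prediction of noncanonical fragments, v1.
# Ordered, first-match-wins substructure rules (package SMARTS subset). For
# each rule one or two ionizable centers are given as pattern atom positions
# with a pKa value and an equilibrium type. A center whose atom was already
# claimed by an earlier rule is skipped; values outside the admissibility
# window are matched (the atom is claimed) but not emitted.
# pKa values are representative means for the functional group, following the
# Dimorphite-DL-derived starting point with medicinal-chemistry additions
# (tetrazole, imidazole, phenols, alpha-amines); amide, sulfonamide and
# iminium nitrogens are excluded from the amine rules by recursive guards.
name	pattern	c1_pos	c1_pka	c1_type	c2_pos	c2_pka	c2_type
sulfate_monoester	[OX2]([#6])[SX4](=[OX1])(=[OX1])[OX2H1]	6	-3.1	acid	NA	NA	NA
sulfonic_acid	[SX4](=[OX1])(=[OX1])[OX2H1]	4	-1.5	acid	NA	NA	NA
phosphate_monoester	[OX2]([#6])[PX4](=[OX1])([OX2H1])[OX2H1]	5	1.9	acid	6	6.7	acid
phosphonic_acid	[PX4](=[OX1])([OX2H1])[OX2H1]	3	2.0	acid	4	7.8	acid
phosphate_diester	[OX2]([#6])[PX4](=[OX1])([OX2]([#6]))[OX2H1]	7	1.5	acid	NA	NA	NA
tetrazole_1H	[cX3]1[nX3H1][nX2][nX2][nX2]1	2	4.9	acid	NA	NA	NA
tetrazole_2H	[cX3]1[nX2][nX3H1][nX2][nX2]1	3	4.9	acid	NA	NA	NA
alpha_carboxylic_acid	[OX2H1][CX3](=[OX1])[CX4][NX3]	1	3.6	acid	NA	NA	NA
carboxylic_acid	[OX2H1][CX3]=[OX1]	1	4.2	acid	NA	NA	NA
imide	[CX3](=[OX1])[NX3H1][CX3]=[OX1]	3	9.6	acid	NA	NA	NA
hydroxamic_acid	[OX2H1][NX3H1][CX3]=[OX1]	1	9.4	acid	NA	NA	NA
aryl_thiol	[SX2H1][cX3]	1	6.6	acid	NA	NA	NA
thiol	[SX2H1][CX4]	1	9.1	acid	NA	NA	NA
phenol	[OX2H1][cX3]	1	9.9	acid	NA	NA	NA
sulfonamide_primary	[NX3H2][SX4](=[OX1])=[OX1]	1	10.3	acid	NA	NA	NA
sulfonamide_secondary	[NX3H1]([#6])[SX4](=[OX1])=[OX1]	1	10.1	acid	NA	NA	NA
guanidine	[NX3][CX3](=[NX2])[NX3]	3	12.5	base	NA	NA	NA
guanidinium	[NX3][CX3](=[NX3H2+1])[NX3]	3	12.5	base	NA	NA	NA
amidine	[CX3](=[NX2])[NX3H2]	2	11.5	base	NA	NA	NA
imidazole	[cX3]1[nX2][cX3][nX3H1][cX3]1	2	6.9	base	NA	NA	NA
imidazolium	[cX3]1[nX3H1+1][cX3][nX3H1][cX3]1	2	6.9	base	NA	NA	NA
pyridine	[nX2]1[cX3][cX3][cX3][cX3][cX3]1	1	5.2	base	NA	NA	NA
pyridinium	[nX3H1+1]1[cX3][cX3][cX3][cX3][cX3]1	1	5.2	base	NA	NA	NA
aniline_primary	[NX3H2][cX3]	1	4.6	base	NA	NA	NA
aniline_secondary	[NX3H1]([CX4])[cX3]	1	4.9	base	NA	NA	NA
alpha_amine_primary	[NX3H2][CX4][CX3]=[OX1]	1	8.0	base	NA	NA	NA
alpha_amine_secondary	[NX3H1;!$([NX3][CX3]=[OX1]);!$([NX3][CX3]=[NX2])]([CX4])[CX4][CX3]=[OX1]	1	8.2	base	NA	NA	NA
primary_amine	[NX3H2;!$([NX3][CX3]=[OX1]);!$([NX3][CX3]=[NX2]);!$([NX3][SX4])][CX4]	1	10.5	base	NA	NA	NA
secondary_amine	[NX3H1;!$([NX3][CX3]=[OX1]);!$([NX3][CX3]=[NX2]);!$([NX3][SX4])]([CX4])[CX4]	1	10.9	base	NA	NA	NA
tertiary_amine	[NX3H0;!$([NX3][CX3]=[OX1]);!$([NX3][CX3]=[NX2]);!$([NX3][SX4]);!$([NX3][cX3])]([CX4])([CX4])[CX4]	1	9.8	base	NA	NA	NA
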