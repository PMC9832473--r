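# pepiso canonical amino-acid templates, v1.
# Substructure templates (package SMARTS subset) for capped fragments of the
# 20 canonical residues. Atom 1 is the backbone nitrogen, atom 2 the alpha
# carbon (except proline/glycine, see patterns). Columns:
#   residue  one-letter code
#   variant  template variant (tautomeric or ionization form)
#   pattern  full residue pattern, caps and C-terminal OH/NH2 excluded
#   c_pos    pattern position of the backbone carbonyl carbon
#   ion_pos  pattern position of the ionizable side-chain atom (0 = none)
#   ion_type acid | base | none
# Matching requires full coverage: every fragment heavy atom must be part of
# the match, a cap, or the single C-terminal substituent (OH or NH2) on c_pos.
# Fragments are neutralized before matching; explicitly charged variants are
# kept for centers neutralization leaves as drawn (imidazolium, guanidinium).
residue	variant	pattern	c_pos	ion_pos	ion_type
W	indole	[NX3][CX4H1]([CX4H2]c1[cX3H1][nX3H1]c2[cX3H1][cX3H1][cX3H1][cX3H1]c12)[CX3]=[OX1]	13	0	none
R	neutral	[NX3][CX4H1]([CX4H2][CX4H2][CX4H2][NX3H1][CX3](=[NX2H1])[NX3H2])[CX3]=[OX1]	10	8	base
R	guanidinium	[NX3][CX4H1]([CX4H2][CX4H2][CX4H2][NX3H1][CX3](=[NX3H2+1])[NX3H2])[CX3]=[OX1]	10	8	base
H	tau_NE2_H	[NX3][CX4H1]([CX4H2]c1[nX2][cX3H1][nX3H1][cX3H1]1)[CX3]=[OX1]	9	5	base
H	tau_ND1_H	[NX3][CX4H1]([CX4H2]c1[nX3H1][cX3H1][nX2][cX3H1]1)[CX3]=[OX1]	9	7	base
H	imidazolium	[NX3][CX4H1]([CX4H2]c1[nX3H1+1][cX3H1][nX3H1][cX3H1]1)[CX3]=[OX1]	9	5	base
Y	phenol	[NX3][CX4H1]([CX4H2]c1[cX3H1][cX3H1][cX3]([OX2H1])[cX3H1][cX3H1]1)[CX3]=[OX1]	11	8	acid
F	phenyl	[NX3][CX4H1]([CX4H2]c1[cX3H1][cX3H1][cX3H1][cX3H1][cX3H1]1)[CX3]=[OX1]	10	0	none
K	amine	[NX3][CX4H1]([CX4H2][CX4H2][CX4H2][CX4H2][NX3H2])[CX3]=[OX1]	8	7	base
Q	amide	[NX3][CX4H1]([CX4H2][CX4H2][CX3](=[OX1])[NX3H2])[CX3]=[OX1]	8	0	none
E	acid	[NX3][CX4H1]([CX4H2][CX4H2][CX3](=[OX1])[OX2H1])[CX3]=[OX1]	8	7	acid
N	amide	[NX3][CX4H1]([CX4H2][CX3](=[OX1])[NX3H2])[CX3]=[OX1]	7	0	none
D	acid	[NX3][CX4H1]([CX4H2][CX3](=[OX1])[OX2H1])[CX3]=[OX1]	7	6	acid
M	thioether	[NX3][CX4H1]([CX4H2][CX4H2][SX2][CX4H3])[CX3]=[OX1]	7	0	none
I	sec_butyl	[NX3][CX4H1]([CX4H1]([CX4H3])[CX4H2][CX4H3])[CX3]=[OX1]	7	0	none
L	isobutyl	[NX3][CX4H1]([CX4H2][CX4H1]([CX4H3])[CX4H3])[CX3]=[OX1]	7	0	none
T	threonine	[NX3][CX4H1]([CX4H1]([OX2H1])[CX4H3])[CX3]=[OX1]	6	0	none
C	thiol	[NX3][CX4H1]([CX4H2][SX2H1])[CX3]=[OX1]	5	4	acid
S	alcohol	[NX3][CX4H1]([CX4H2][OX2H1])[CX3]=[OX1]	5	0	none
V	isopropyl	[NX3][CX4H1]([CX4H1]([CX4H3])[CX4H3])[CX3]=[OX1]	6	0	none
P	pyrrolidine	[NX3]1[CX4H1]([CX3]=[OX1])[CX4H2][CX4H2][CX4H2]1	3	0	none
A	methyl	[NX3][CX4H1]([CX4H3])[CX3]=[OX1]	4	0	none
G	glycine	[NX3][CX4H2][CX3]=[OX1]	3	0	none
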