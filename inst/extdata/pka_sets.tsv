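# pepiso canonical pKa sets, v1.
# One row per pKa value. Columns:
#   set        pKa-set identifier
#   parameter  nterm | cterm | sidechain
#   residue    one-letter residue code, or * for the set default
#   position   any | n_terminal | internal | c_terminal (side-chain values only)
#   pka        pKa in pH units
# The six position-independent sets carry the nine published values each
# (N-terminus, C-terminus, and the seven ionizable side chains C Y D E H K R).
# The per-residue terminus values of the Gauci set and the per-residue /
# positional values of the ProMoST set are transcribed from the publicly
# available pIR source code and ProMoST web resource lineage (extended
# Bjellqvist family); they are externally derived data, not measured here.
set	parameter	residue	position	pka
IPC_peptide	nterm	*	any	9.564
IPC_peptide	cterm	*	any	2.383
IPC_peptide	sidechain	C	any	8.297
IPC_peptide	sidechain	Y	any	10.071
IPC_peptide	sidechain	D	any	3.887
IPC_peptide	sidechain	E	any	4.317
IPC_peptide	sidechain	H	any	6.018
IPC_peptide	sidechain	K	any	10.517
IPC_peptide	sidechain	R	any	12.503
IPC2_peptide	nterm	*	any	7.947
IPC2_peptide	cterm	*	any	2.977
IPC2_peptide	sidechain	C	any	9.439
IPC2_peptide	sidechain	Y	any	9.153
IPC2_peptide	sidechain	D	any	3.969
IPC2_peptide	sidechain	E	any	4.507
IPC2_peptide	sidechain	H	any	6.439
IPC2_peptide	sidechain	K	any	8.165
IPC2_peptide	sidechain	R	any	11.493
Gauci	nterm	*	any	7.5
Gauci	nterm	A	any	7.59
Gauci	nterm	M	any	7.0
Gauci	nterm	S	any	6.93
Gauci	nterm	P	any	8.36
Gauci	nterm	T	any	6.82
Gauci	nterm	V	any	7.44
Gauci	nterm	E	any	7.7
Gauci	nterm	C	any	6.5
Gauci	nterm	N	any	7.22
Gauci	cterm	*	any	3.55
Gauci	cterm	D	any	4.55
Gauci	cterm	E	any	4.75
Gauci	sidechain	C	any	9.0
Gauci	sidechain	Y	any	10.0
Gauci	sidechain	D	any	4.05
Gauci	sidechain	E	any	4.45
Gauci	sidechain	H	any	5.98
Gauci	sidechain	K	any	10.0
Gauci	sidechain	R	any	12.0
Grimsley	nterm	*	any	7.7
Grimsley	cterm	*	any	3.3
Grimsley	sidechain	C	any	6.8
Grimsley	sidechain	Y	any	10.3
Grimsley	sidechain	D	any	3.5
Grimsley	sidechain	E	any	4.2
Grimsley	sidechain	H	any	6.6
Grimsley	sidechain	K	any	10.5
Grimsley	sidechain	R	any	12.04
Toseland	nterm	*	any	8.71
Toseland	cterm	*	any	3.19
Toseland	sidechain	C	any	6.87
Toseland	sidechain	Y	any	9.61
Toseland	sidechain	D	any	3.6
Toseland	sidechain	E	any	4.29
Toseland	sidechain	H	any	6.33
Toseland	sidechain	K	any	10.45
Toseland	sidechain	R	any	12.0
Thurlkill	nterm	*	any	8.0
Thurlkill	cterm	*	any	3.67
Thurlkill	sidechain	C	any	8.55
Thurlkill	sidechain	Y	any	9.84
Thurlkill	sidechain	D	any	3.67
Thurlkill	sidechain	E	any	4.25
Thurlkill	sidechain	H	any	6.54
Thurlkill	sidechain	K	any	10.4
Thurlkill	sidechain	R	any	12.0
Lehninger	nterm	*	any	9.69
Lehninger	cterm	*	any	2.34
Lehninger	sidechain	C	any	8.33
Lehninger	sidechain	Y	any	10.0
Lehninger	sidechain	D	any	3.86
Lehninger	sidechain	E	any	4.25
Lehninger	sidechain	H	any	6.0
Lehninger	sidechain	K	any	10.5
Lehninger	sidechain	R	any	12.4
ProMoST	nterm	*	any	7.5
ProMoST	nterm	G	any	7.5
ProMoST	nterm	A	any	7.58
ProMoST	nterm	S	any	6.86
ProMoST	nterm	P	any	8.36
ProMoST	nterm	T	any	7.02
ProMoST	nterm	V	any	7.44
ProMoST	nterm	M	any	7.0
ProMoST	nterm	E	any	7.7
ProMoST	nterm	D	any	7.7
ProMoST	nterm	C	any	8.0
ProMoST	nterm	I	any	7.48
ProMoST	nterm	L	any	7.46
ProMoST	nterm	F	any	6.96
ProMoST	nterm	W	any	7.11
ProMoST	nterm	Y	any	6.83
ProMoST	nterm	H	any	7.18
ProMoST	nterm	K	any	6.67
ProMoST	nterm	R	any	6.76
ProMoST	nterm	Q	any	6.85
ProMoST	nterm	N	any	7.22
ProMoST	cterm	*	any	3.7
ProMoST	cterm	G	any	3.7
ProMoST	cterm	A	any	3.75
ProMoST	cterm	S	any	3.61
ProMoST	cterm	P	any	3.44
ProMoST	cterm	T	any	3.55
ProMoST	cterm	V	any	3.69
ProMoST	cterm	M	any	3.68
ProMoST	cterm	E	any	3.65
ProMoST	cterm	D	any	3.4
ProMoST	cterm	C	any	3.17
ProMoST	cterm	I	any	3.72
ProMoST	cterm	L	any	3.73
ProMoST	cterm	F	any	3.98
ProMoST	cterm	W	any	3.78
ProMoST	cterm	Y	any	3.6
ProMoST	cterm	H	any	3.33
ProMoST	cterm	K	any	3.4
ProMoST	cterm	R	any	3.41
ProMoST	cterm	Q	any	3.57
ProMoST	cterm	N	any	3.64
ProMoST	sidechain	D	internal	4.07
ProMoST	sidechain	D	n_terminal	3.57
ProMoST	sidechain	D	c_terminal	4.57
ProMoST	sidechain	E	internal	4.45
ProMoST	sidechain	E	n_terminal	4.15
ProMoST	sidechain	E	c_terminal	4.75
ProMoST	sidechain	C	internal	8.28
ProMoST	sidechain	C	n_terminal	8.0
ProMoST	sidechain	C	c_terminal	9.0
ProMoST	sidechain	Y	internal	9.84
ProMoST	sidechain	Y	n_terminal	9.34
ProMoST	sidechain	Y	c_terminal	10.34
ProMoST	sidechain	H	internal	6.08
ProMoST	sidechain	H	n_terminal	4.89
ProMoST	sidechain	H	c_terminal	6.89
ProMoST	sidechain	K	internal	9.8
ProMoST	sidechain	K	n_terminal	10.0
ProMoST	sidechain	K	c_terminal	10.3
ProMoST	sidechain	R	internal	12.5
ProMoST	sidechain	R	n_terminal	11.5
ProMoST	sidechain	R	c_terminal	12.5
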