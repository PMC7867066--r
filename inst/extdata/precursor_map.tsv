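# Carbon precursor origins for the 20 standard amino acids in E. coli grown
# on glucose as sole carbon source (M9 minimal medium).
#
# Each carbon site maps to exactly one precursor molecule instance within the
# residue.  Atoms sharing a `molecule` id derive from one and the same
# precursor molecule, so under fractional labeling with U-13C6 glucose they
# are either all 13C (intact unit) or independently labeled at natural
# abundance.  `precursor_carbon` is the carbon index within that precursor;
# covalently bonded atoms of one molecule carry adjacent indices (intact
# bond).  `family` tags the metabolic origin; oxaloacetate and 2-oxoglutarate
# units pass through the TCA cycle and are subject to bond scrambling
# (aeration-dependent), controlled by the scheme's `scramble` parameter.
#
# Side-chain conventions for diastereotopic methyls: Val CG1 / Leu CD1 carry
# the methyl retained on the ketoacid skeleton (intact bond to the attached
# carbon, pro-R); Val CG2 / Leu CD2 carry the methyl migrated by ketol-acid
# reductoisomerase (bond to the attached carbon broken, pro-S).
#
# One-carbon units (Met CE, His CE1) come from the serine/THF pool and are
# tagged 3-phosphoglycerate; Arg CZ comes from CO2 fixed via carbamoyl
# phosphate and is tagged pyruvate (dominant decarboxylation source); neither
# participates in any carbon-carbon bond of the residue.
residue	atom	molecule	family	precursor_carbon
ALA	C	pyr1	pyruvate	1
ALA	CA	pyr1	pyruvate	2
ALA	CB	pyr1	pyruvate	3
ARG	C	og1	2-oxoglutarate	1
ARG	CA	og1	2-oxoglutarate	2
ARG	CB	og1	2-oxoglutarate	3
ARG	CG	aca1	acetyl-CoA	2
ARG	CD	aca1	acetyl-CoA	1
ARG	CZ	co2a	pyruvate	1
ASN	C	oaa1	oxaloacetate	1
ASN	CA	oaa1	oxaloacetate	2
ASN	CB	oaa1	oxaloacetate	3
ASN	CG	oaa1	oxaloacetate	4
ASP	C	oaa1	oxaloacetate	1
ASP	CA	oaa1	oxaloacetate	2
ASP	CB	oaa1	oxaloacetate	3
ASP	CG	oaa1	oxaloacetate	4
CYS	C	pga1	3-phosphoglycerate	1
CYS	CA	pga1	3-phosphoglycerate	2
CYS	CB	pga1	3-phosphoglycerate	3
GLN	C	og1	2-oxoglutarate	1
GLN	CA	og1	2-oxoglutarate	2
GLN	CB	og1	2-oxoglutarate	3
GLN	CG	aca1	acetyl-CoA	2
GLN	CD	aca1	acetyl-CoA	1
GLU	C	og1	2-oxoglutarate	1
GLU	CA	og1	2-oxoglutarate	2
GLU	CB	og1	2-oxoglutarate	3
GLU	CG	aca1	acetyl-CoA	2
GLU	CD	aca1	acetyl-CoA	1
GLY	C	pga1	3-phosphoglycerate	1
GLY	CA	pga1	3-phosphoglycerate	2
HIS	C	ppp1	pentose-phosphate	1
HIS	CA	ppp1	pentose-phosphate	2
HIS	CB	ppp1	pentose-phosphate	3
HIS	CG	ppp1	pentose-phosphate	4
HIS	CD2	ppp1	pentose-phosphate	5
HIS	CE1	c1a	3-phosphoglycerate	1
ILE	C	oaa1	oxaloacetate	1
ILE	CA	oaa1	oxaloacetate	2
ILE	CG1	oaa1	oxaloacetate	3
ILE	CD1	oaa1	oxaloacetate	4
ILE	CB	pyr1	pyruvate	2
ILE	CG2	pyr1	pyruvate	3
LEU	C	aca1	acetyl-CoA	1
LEU	CA	aca1	acetyl-CoA	2
LEU	CB	pyr1	pyruvate	2
LEU	CD2	pyr1	pyruvate	3
LEU	CG	pyr2	pyruvate	2
LEU	CD1	pyr2	pyruvate	3
LYS	C	oaa1	oxaloacetate	1
LYS	CA	oaa1	oxaloacetate	2
LYS	CB	oaa1	oxaloacetate	3
LYS	CG	oaa1	oxaloacetate	4
LYS	CD	pyr1	pyruvate	3
LYS	CE	pyr1	pyruvate	2
MET	C	oaa1	oxaloacetate	1
MET	CA	oaa1	oxaloacetate	2
MET	CB	oaa1	oxaloacetate	3
MET	CG	oaa1	oxaloacetate	4
MET	CE	c1a	3-phosphoglycerate	1
PHE	C	pep1	PEP/E4P	1
PHE	CA	pep1	PEP/E4P	2
PHE	CB	pep1	PEP/E4P	3
PHE	CG	pep2	PEP/E4P	2
PHE	CD2	pep2	PEP/E4P	3
PHE	CD1	e4p1	PEP/E4P	1
PHE	CE1	e4p1	PEP/E4P	2
PHE	CZ	e4p1	PEP/E4P	3
PHE	CE2	e4p1	PEP/E4P	4
PRO	C	og1	2-oxoglutarate	1
PRO	CA	og1	2-oxoglutarate	2
PRO	CB	og1	2-oxoglutarate	3
PRO	CG	aca1	acetyl-CoA	2
PRO	CD	aca1	acetyl-CoA	1
SER	C	pga1	3-phosphoglycerate	1
SER	CA	pga1	3-phosphoglycerate	2
SER	CB	pga1	3-phosphoglycerate	3
THR	C	oaa1	oxaloacetate	1
THR	CA	oaa1	oxaloacetate	2
THR	CB	oaa1	oxaloacetate	3
THR	CG2	oaa1	oxaloacetate	4
TRP	C	pga1	3-phosphoglycerate	1
TRP	CA	pga1	3-phosphoglycerate	2
TRP	CB	pga1	3-phosphoglycerate	3
TRP	CG	ppp1	pentose-phosphate	1
TRP	CD1	ppp1	pentose-phosphate	2
TRP	CD2	pep1	PEP/E4P	2
TRP	CE2	pep1	PEP/E4P	3
TRP	CE3	e4p1	PEP/E4P	1
TRP	CZ3	e4p1	PEP/E4P	2
TRP	CH2	e4p1	PEP/E4P	3
TRP	CZ2	e4p1	PEP/E4P	4
TYR	C	pep1	PEP/E4P	1
TYR	CA	pep1	PEP/E4P	2
TYR	CB	pep1	PEP/E4P	3
TYR	CG	pep2	PEP/E4P	2
TYR	CD2	pep2	PEP/E4P	3
TYR	CD1	e4p1	PEP/E4P	1
TYR	CE1	e4p1	PEP/E4P	2
TYR	CZ	e4p1	PEP/E4P	3
TYR	CE2	e4p1	PEP/E4P	4
VAL	C	pyr1	pyruvate	1
VAL	CA	pyr1	pyruvate	2
VAL	CG2	pyr1	pyruvate	3
VAL	CB	pyr2	pyruvate	2
VAL	CG1	pyr2	pyruvate	3
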