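# Covalent carbon-carbon bonds of the 20 standard amino-acid residues
# (backbone carbonyl is named C, PDB atom-name conventions).  Used to
# validate bond queries and to derive the intact-bond set: a bond is intact
# when both atoms belong to the same precursor molecule (see
# precursor_map.tsv) with adjacent precursor carbon indices.
residue	atom1	atom2
ALA	C	CA
ALA	CA	CB
ARG	C	CA
ARG	CA	CB
ARG	CB	CG
ARG	CG	CD
ASN	C	CA
ASN	CA	CB
ASN	CB	CG
ASP	C	CA
ASP	CA	CB
ASP	CB	CG
CYS	C	CA
CYS	CA	CB
GLN	C	CA
GLN	CA	CB
GLN	CB	CG
GLN	CG	CD
GLU	C	CA
GLU	CA	CB
GLU	CB	CG
GLU	CG	CD
GLY	C	CA
HIS	C	CA
HIS	CA	CB
HIS	CB	CG
HIS	CG	CD2
ILE	C	CA
ILE	CA	CB
ILE	CB	CG1
ILE	CB	CG2
ILE	CG1	CD1
LEU	C	CA
LEU	CA	CB
LEU	CB	CG
LEU	CG	CD1
LEU	CG	CD2
LYS	C	CA
LYS	CA	CB
LYS	CB	CG
LYS	CG	CD
LYS	CD	CE
MET	C	CA
MET	CA	CB
MET	CB	CG
PHE	C	CA
PHE	CA	CB
PHE	CB	CG
PHE	CG	CD1
PHE	CG	CD2
PHE	CD1	CE1
PHE	CD2	CE2
PHE	CE1	CZ
PHE	CE2	CZ
PRO	C	CA
PRO	CA	CB
PRO	CB	CG
PRO	CG	CD
SER	C	CA
SER	CA	CB
THR	C	CA
THR	CA	CB
THR	CB	CG2
TRP	C	CA
TRP	CA	CB
TRP	CB	CG
TRP	CG	CD1
TRP	CG	CD2
TRP	CD2	CE2
TRP	CD2	CE3
TRP	CE3	CZ3
TRP	CZ3	CH2
TRP	CH2	CZ2
TRP	CZ2	CE2
TYR	C	CA
TYR	CA	CB
TYR	CB	CG
TYR	CG	CD1
TYR	CG	CD2
TYR	CD1	CE1
TYR	CD2	CE2
TYR	CE1	CZ
TYR	CE2	CZ
VAL	C	CA
VAL	CA	CB
VAL	CB	CG1
VAL	CB	CG2
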