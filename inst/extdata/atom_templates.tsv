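residue	atom	donor	acceptor	aromatic	cationic	anionic
ALA	N	1	0	0	0	0
ARG	N	1	0	0	0	0
ASN	N	1	0	0	0	0
ASP	N	1	0	0	0	0
CYS	N	1	0	0	0	0
GLN	N	1	0	0	0	0
GLU	N	1	0	0	0	0
GLY	N	1	0	0	0	0
HIS	N	1	0	0	0	0
ILE	N	1	0	0	0	0
LEU	N	1	0	0	0	0
LYS	N	1	0	0	0	0
MET	N	1	0	0	0	0
PHE	N	1	0	0	0	0
SER	N	1	0	0	0	0
THR	N	1	0	0	0	0
TRP	N	1	0	0	0	0
TYR	N	1	0	0	0	0
VAL	N	1	0	0	0	0
PRO	N	0	0	0	0	0
ALA	O	0	1	0	0	0
ALA	OXT	0	1	0	0	1
ARG	O	0	1	0	0	0
ARG	OXT	0	1	0	0	1
ASN	O	0	1	0	0	0
ASN	OXT	0	1	0	0	1
ASP	O	0	1	0	0	0
ASP	OXT	0	1	0	0	1
CYS	O	0	1	0	0	0
CYS	OXT	0	1	0	0	1
GLN	O	0	1	0	0	0
GLN	OXT	0	1	0	0	1
GLU	O	0	1	0	0	0
GLU	OXT	0	1	0	0	1
GLY	O	0	1	0	0	0
GLY	OXT	0	1	0	0	1
HIS	O	0	1	0	0	0
HIS	OXT	0	1	0	0	1
ILE	O	0	1	0	0	0
ILE	OXT	0	1	0	0	1
LEU	O	0	1	0	0	0
LEU	OXT	0	1	0	0	1
LYS	O	0	1	0	0	0
LYS	OXT	0	1	0	0	1
MET	O	0	1	0	0	0
MET	OXT	0	1	0	0	1
PHE	O	0	1	0	0	0
PHE	OXT	0	1	0	0	1
PRO	O	0	1	0	0	0
PRO	OXT	0	1	0	0	1
SER	O	0	1	0	0	0
SER	OXT	0	1	0	0	1
THR	O	0	1	0	0	0
THR	OXT	0	1	0	0	1
TRP	O	0	1	0	0	0
TRP	OXT	0	1	0	0	1
TYR	O	0	1	0	0	0
TYR	OXT	0	1	0	0	1
VAL	O	0	1	0	0	0
VAL	OXT	0	1	0	0	1
ARG	NE	1	0	0	1	0
ARG	NH1	1	0	0	1	0
ARG	NH2	1	0	0	1	0
LYS	NZ	1	0	0	1	0
HIS	ND1	1	1	1	0	0
HIS	NE2	1	1	1	0	0
HIS	CG	0	0	1	0	0
HIS	CD2	0	0	1	0	0
HIS	CE1	0	0	1	0	0
ASP	OD1	0	1	0	0	1
ASP	OD2	0	1	0	0	1
GLU	OE1	0	1	0	0	1
GLU	OE2	0	1	0	0	1
ASN	OD1	0	1	0	0	0
ASN	ND2	1	0	0	0	0
GLN	OE1	0	1	0	0	0
GLN	NE2	1	0	0	0	0
SER	OG	1	1	0	0	0
THR	OG1	1	1	0	0	0
CYS	SG	1	1	0	0	0
TYR	OH	1	1	0	0	0
TYR	CG	0	0	1	0	0
TYR	CD1	0	0	1	0	0
TYR	CD2	0	0	1	0	0
TYR	CE1	0	0	1	0	0
TYR	CE2	0	0	1	0	0
TYR	CZ	0	0	1	0	0
PHE	CG	0	0	1	0	0
PHE	CD1	0	0	1	0	0
PHE	CD2	0	0	1	0	0
PHE	CE1	0	0	1	0	0
PHE	CE2	0	0	1	0	0
PHE	CZ	0	0	1	0	0
TRP	NE1	1	0	1	0	0
TRP	CG	0	0	1	0	0
TRP	CD1	0	0	1	0	0
TRP	CD2	0	0	1	0	0
TRP	CE2	0	0	1	0	0
TRP	CE3	0	0	1	0	0
TRP	CZ2	0	0	1	0	0
TRP	CZ3	0	0	1	0	0
TRP	CH2	0	0	1	0	0
HOH	O	1	1	0	0	0
G4P	N1	1	0	1	0	0
G4P	C2	0	0	1	0	0
G4P	N2	1	0	0	0	0
G4P	N3	0	1	1	0	0
G4P	C4	0	0	1	0	0
G4P	C5	0	0	1	0	0
G4P	C6	0	0	1	0	0
G4P	C8	0	0	1	0	0
G4P	O6	0	1	0	0	0
G4P	N7	0	1	1	0	0
G4P	N9	0	1	1	0	0
G4P	C1'	0	0	0	0	0
G4P	C2'	0	0	0	0	0
G4P	C3'	0	0	0	0	0
G4P	C4'	0	0	0	0	0
G4P	C5'	0	0	0	0	0
G4P	O2'	1	1	0	0	0
G4P	O3'	0	1	0	0	0
G4P	O4'	0	1	0	0	0
G4P	O5'	0	1	0	0	0
G4P	PA	0	0	0	0	0
G4P	PB	0	0	0	0	0
G4P	PC	0	0	0	0	0
G4P	PD	0	0	0	0	0
G4P	O1A	0	1	0	0	1
G4P	O2A	0	1	0	0	1
G4P	O3A	0	1	0	0	0
G4P	O1C	0	1	0	0	1
G4P	O2C	0	1	0	0	1
G4P	O3C	0	1	0	0	0
G4P	O1D	0	1	0	0	1
G4P	O2D	0	1	0	0	1
G4P	O3D	0	1	0	0	1
G4P	O1B	0	1	0	0	1
G4P	O2B	0	1	0	0	1
G4P	O3B	0	1	0	0	1
C1Z	N1	1	0	1	0	0
C1Z	C2	0	0	1	0	0
C1Z	N2	1	0	0	0	0
C1Z	N3	0	1	1	0	0
C1Z	C4	0	0	1	0	0
C1Z	C5	0	0	1	0	0
C1Z	C6	0	0	1	0	0
C1Z	C8	0	0	1	0	0
C1Z	O6	0	1	0	0	0
C1Z	N7	0	1	1	0	0
C1Z	N9	0	1	1	0	0
C1Z	C1'	0	0	0	0	0
C1Z	C2'	0	0	0	0	0
C1Z	C3'	0	0	0	0	0
C1Z	C4'	0	0	0	0	0
C1Z	C5'	0	0	0	0	0
C1Z	O2'	1	1	0	0	0
C1Z	O3'	0	1	0	0	0
C1Z	O4'	0	1	0	0	0
C1Z	O5'	0	1	0	0	0
C1Z	PA	0	0	0	0	0
C1Z	PB	0	0	0	0	0
C1Z	PC	0	0	0	0	0
C1Z	PD	0	0	0	0	0
C1Z	O1A	0	1	0	0	1
C1Z	O2A	0	1	0	0	1
C1Z	O3A	0	1	0	0	0
C1Z	O1C	0	1	0	0	1
C1Z	O2C	0	1	0	0	1
C1Z	O3C	0	1	0	0	0
C1Z	O1D	0	1	0	0	1
C1Z	O2D	0	1	0	0	1
C1Z	O3D	0	1	0	0	1
C1Z	O1B	0	1	0	0	1
C1Z	O2B	0	1	0	0	1
C1Z	O3B	0	1	0	0	0
C1Z	PG	0	0	0	0	0
C1Z	O1G	0	1	0	0	1
C1Z	O2G	0	1	0	0	1
C1Z	O3G	0	1	0	0	1
0O2	N1	1	0	1	0	0
0O2	C2	0	0	1	0	0
0O2	N2	1	0	0	0	0
0O2	N3	0	1	1	0	0
0O2	C4	0	0	1	0	0
0O2	C5	0	0	1	0	0
0O2	C6	0	0	1	0	0
0O2	C8	0	0	1	0	0
0O2	O6	0	1	0	0	0
0O2	N7	0	1	1	0	0
0O2	N9	0	1	1	0	0
0O2	C1'	0	0	0	0	0
0O2	C2'	0	0	0	0	0
0O2	C3'	0	0	0	0	0
0O2	C4'	0	0	0	0	0
0O2	C5'	0	0	0	0	0
0O2	O2'	1	1	0	0	0
0O2	O3'	0	1	0	0	0
0O2	O4'	0	1	0	0	0
0O2	O5'	0	1	0	0	0
0O2	PA	0	0	0	0	0
0O2	PB	0	0	0	0	0
0O2	PC	0	0	0	0	0
0O2	PD	0	0	0	0	0
0O2	O1A	0	1	0	0	1
0O2	O2A	0	1	0	0	1
0O2	O3A	0	1	0	0	0
0O2	O1C	0	1	0	0	1
0O2	O2C	0	1	0	0	1
0O2	O3C	0	1	0	0	0
0O2	O1D	0	1	0	0	1
0O2	O2D	0	1	0	0	1
0O2	O3D	0	1	0	0	1
0O2	O1B	0	1	0	0	1
0O2	O2B	0	1	0	0	1
0O2	O3B	0	1	0	0	0
0O2	PG	0	0	0	0	0
0O2	O1G	0	1	0	0	1
0O2	O2G	0	1	0	0	1
0O2	O3G	0	1	0	0	1
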