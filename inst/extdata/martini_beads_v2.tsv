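# ddscore coarse-grained side-chain bead mapping, version 2 (MARTINI 2.x
# amino-acid definitions). One backbone bead "BB" per residue (centroid of
# N/CA/C/O) is implicit; this table lists side-chain beads only.
# Columns: res_type <TAB> bead <TAB> space-separated heavy-atom names.
# ALA and GLY carry no side-chain bead.
ARG	SC1	CB CG CD
ARG	SC2	NE CZ NH1 NH2
ASN	SC1	CB CG OD1 ND2
ASP	SC1	CB CG OD1 OD2
CYS	SC1	CB SG
GLN	SC1	CB CG CD OE1 NE2
GLU	SC1	CB CG CD OE1 OE2
HIS	SC1	CB CG
HIS	SC2	CD2 NE2
HIS	SC3	ND1 CE1
ILE	SC1	CB CG1 CG2 CD1
LEU	SC1	CB CG CD1 CD2
LYS	SC1	CB CG CD
LYS	SC2	CE NZ
MET	SC1	CB CG SD CE
PHE	SC1	CB CG
PHE	SC2	CD1 CE1
PHE	SC3	CD2 CE2 CZ
PRO	SC1	CB CG CD
SER	SC1	CB OG
THR	SC1	CB OG1 CG2
TRP	SC1	CB CG CD1
TRP	SC2	NE1 CE2
TRP	SC3	CD2 CE3
TRP	SC4	CZ2 CZ3 CH2
TYR	SC1	CB CG
TYR	SC2	CD1 CE1
TYR	SC3	CD2 CE2 CZ OH
VAL	SC1	CB CG1 CG2
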