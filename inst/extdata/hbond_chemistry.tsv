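resid	role	heavy	hydrogen
ALA	donor	N	H
ARG	donor	N	H
ASN	donor	N	H
ASP	donor	N	H
CYS	donor	N	H
GLN	donor	N	H
GLU	donor	N	H
GLY	donor	N	H
HIS	donor	N	H
ILE	donor	N	H
LEU	donor	N	H
LYS	donor	N	H
MET	donor	N	H
PHE	donor	N	H
SER	donor	N	H
THR	donor	N	H
TRP	donor	N	H
TYR	donor	N	H
VAL	donor	N	H
ARG	donor	NE	HE
ARG	donor	NH1	HH11
ARG	donor	NH1	HH12
ARG	donor	NH2	HH21
ARG	donor	NH2	HH22
ASN	donor	ND2	HD21
ASN	donor	ND2	HD22
CYS	donor	SG	HG
GLN	donor	NE2	HE21
GLN	donor	NE2	HE22
HIS	donor	ND1	HD1
HIS	donor	NE2	HE2
LYS	donor	NZ	HZ1
LYS	donor	NZ	HZ2
LYS	donor	NZ	HZ3
SER	donor	OG	HG
THR	donor	OG1	HG1
TRP	donor	NE1	HE1
TYR	donor	OH	HH
NAP	donor	N6A	H61
NAP	donor	N6A	H62
NAP	donor	N7N	H71
NAP	donor	N7N	H72
NAD	donor	N6A	H61
NAD	donor	N6A	H62
NAD	donor	N7N	H71
NAD	donor	N7N	H72
ALA	acceptor	O
ARG	acceptor	O
ASN	acceptor	O
ASP	acceptor	O
CYS	acceptor	O
GLN	acceptor	O
GLU	acceptor	O
GLY	acceptor	O
HIS	acceptor	O
ILE	acceptor	O
LEU	acceptor	O
LYS	acceptor	O
MET	acceptor	O
PHE	acceptor	O
PRO	acceptor	O
SER	acceptor	O
THR	acceptor	O
TRP	acceptor	O
TYR	acceptor	O
VAL	acceptor	O
ASN	acceptor	OD1
ASP	acceptor	OD1
ASP	acceptor	OD2
GLN	acceptor	OE1
GLU	acceptor	OE1
GLU	acceptor	OE2
HIS	acceptor	ND1
HIS	acceptor	NE2
MET	acceptor	SD
SER	acceptor	OG
THR	acceptor	OG1
TYR	acceptor	OH
NAP	acceptor	N1A
NAP	acceptor	N3A
NAP	acceptor	N7A
NAP	acceptor	O7N
NAP	acceptor	O1A
NAP	acceptor	O2A
NAP	acceptor	O1N
NAP	acceptor	O2N
NAP	acceptor	O1X
NAP	acceptor	O2X
NAP	acceptor	O3X
NAP	acceptor	O2B
NAP	acceptor	O3B
NAP	acceptor	O4B
NAP	acceptor	O2D
NAP	acceptor	O3D
NAP	acceptor	O4D
NAP	acceptor	O5B
NAP	acceptor	O5D
NAP	acceptor	O3
NAD	acceptor	N1A
NAD	acceptor	N3A
NAD	acceptor	N7A
NAD	acceptor	O7N
NAD	acceptor	O1A
NAD	acceptor	O2A
NAD	acceptor	O1N
NAD	acceptor	O2N
NAD	acceptor	O2B
NAD	acceptor	O3B
NAD	acceptor	O4B
NAD	acceptor	O2D
NAD	acceptor	O3D
NAD	acceptor	O4D
NAD	acceptor	O5B
NAD	acceptor	O5D
NAD	acceptor	O3
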