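name	recognition	cut_offset
PaeI	GCATGC	5
SphI	GCATGC	5
EcoRI	GAATTC	1
BamHI	GGATCC	1
HindIII	AAGCTT	1
PstI	CTGCAG	5
SmaI	CCCGGG	3
KpnI	GGTACC	5
XbaI	TCTAGA	1
SalI	GTCGAC	1
HinfI	GANTC	1
DdeI	CTNAG	1
AluI	AGCT	2
RsaI	GTAC	2
TaqI	TCGA	1
HaeIII	GGCC	2
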