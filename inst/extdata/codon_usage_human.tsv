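codon	amino_acid	fraction
GCA	A	0.2277227722772
GCC	A	0.3960396039604
GCG	A	0.1089108910891
GCT	A	0.2673267326733
TGC	C	0.5400000000000
TGT	C	0.4600000000000
GAC	D	0.5400000000000
GAT	D	0.4600000000000
GAA	E	0.4200000000000
GAG	E	0.5800000000000
TTC	F	0.5400000000000
TTT	F	0.4600000000000
GGA	G	0.2500000000000
GGC	G	0.3400000000000
GGG	G	0.2500000000000
GGT	G	0.1600000000000
CAC	H	0.5800000000000
CAT	H	0.4200000000000
ATA	I	0.1700000000000
ATC	I	0.4700000000000
ATT	I	0.3600000000000
AAA	K	0.4300000000000
AAG	K	0.5700000000000
CTA	L	0.0693069306931
CTC	L	0.1980198019802
CTG	L	0.3960396039604
CTT	L	0.1287128712871
TTA	L	0.0792079207921
TTG	L	0.1287128712871
ATG	M	1.0000000000000
AAC	N	0.5300000000000
AAT	N	0.4700000000000
CCA	P	0.2800000000000
CCC	P	0.3200000000000
CCG	P	0.1100000000000
CCT	P	0.2900000000000
CAA	Q	0.2700000000000
CAG	Q	0.7300000000000
AGA	R	0.2121212121212
AGG	R	0.2121212121212
CGA	R	0.1111111111111
CGC	R	0.1818181818182
CGG	R	0.2020202020202
CGT	R	0.0808080808081
AGC	S	0.2400000000000
AGT	S	0.1500000000000
TCA	S	0.1500000000000
TCC	S	0.2200000000000
TCG	S	0.0500000000000
TCT	S	0.1900000000000
ACA	T	0.2800000000000
ACC	T	0.3600000000000
ACG	T	0.1100000000000
ACT	T	0.2500000000000
GTA	V	0.1200000000000
GTC	V	0.2400000000000
GTG	V	0.4600000000000
GTT	V	0.1800000000000
TGG	W	1.0000000000000
TAC	Y	0.5600000000000
TAT	Y	0.4400000000000
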