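codon	amino_acid
TTT	F
TTC	F
TTA	L
TTG	L
CTT	L
CTC	L
CTA	L
CTG	L
ATT	I
ATC	I
ATA	M
ATG	M
GTT	V
GTC	V
GTA	V
GTG	V
TCT	S
TCC	S
TCA	S
TCG	S
CCT	P
CCC	P
CCA	P
CCG	P
ACT	T
ACC	T
ACA	T
ACG	T
GCT	A
GCC	A
GCA	A
GCG	A
TAT	Y
TAC	Y
TAA	*
TAG	*
CAT	H
CAC	H
CAA	Q
CAG	Q
AAT	N
AAC	N
AAA	K
AAG	K
GAT	D
GAC	D
GAA	E
GAG	E
TGT	C
TGC	C
TGA	W
TGG	W
CGT	R
CGC	R
CGA	R
CGG	R
AGT	S
AGC	S
AGA	*
AGG	*
GGT	G
GGC	G
GGA	G
GGG	G
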