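No.	Type	Coordination of multiple sequence alignments	Strains	Base changes	Position
1	Insertion	4209-4210	KR.1D, KR.5D	- to CC	Intergenic
2	Insertion	27476-27486	KR.1D	- to TGGGCCCCCC	Intergenic
3	SNP	27487	KR.1D	A to C	Intergenic
4	Deletion	32727-32728	KR.5D	CC to -	Intergenic
5	SNP	37574	KR.5D	A to T	L to Q in ATP synthase F0 subunit
6	Insertion	38727	KR.1D	- to G	Intergenic
7	Deletion	38728-38730	KR.5D	GGG to -	Intergenic
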