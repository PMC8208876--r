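No.	Species	No. of mitogenomes	Aligned length (bp)	No. of SNPs	SNP coverage (%)	No. of INDELs	INDEL coverage (%)
1	Ophiocordyceps sinensis	3	157606	16	0.010	144	0.091
2	Hirsutella thompsonii	3	66635	281	0.42	6489	9.74
3	Hirsutella rhossiliensis	2	64858	7	0.01	2008	3.10
4	Tolypocladium inflatum	5	25338	30	0.12	375	1.48
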