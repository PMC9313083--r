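gene_id	lc	bc	lk	total
ZBTB16	9	4	3	16
KLF4	9	4	1	14
TAL1	9	3	2	14
FOXM1	9	2	1	12
BZW2	9	1	1	11
HLF	8	3	1	12
GPRASP1	8	2	2	12
MNDA	8	2	1	11
PKNOX2	8	1	1	10
TFAP2C	8	1	1	10
SOX4	10	1	2	13
EGR1	7	4	3	14
FOSB	7	4	1	12
SOX17	10	3	0	13
EPAS1	8	3	0	11
KLF2	8	3	0	11
ID4	8	3	0	11
MEIS1	8	2	0	10
MYBL2	8	2	0	10
NR2F1	8	2	0	10
DLX5	8	1	0	9
TBX5	8	1	0	9
NR4A3	8	0	1	9
ID2	7	0	3	10
ETV4	7	0	1	8
SOX12	7	0	1	8
TCF3	7	0	1	8
RORA	6	0	2	8
FOXF1	8	0	0	8
HOXC6	8	0	0	8
RFX2	8	0	0	8
GATA6	7	0	0	7
RARA	7	0	0	7
PAX9	7	0	0	7
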