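gene_symbol	n_datasets	occurrences	notes
APITD1	3	2	CENPS
AURKB	3	0	
BIRC5	3	1	
BUB1	3	20	
BUB1B	3	30	
BUB3	3	0	
C14orf106	2	0	Mis18BP1
C21orf45	2	1	Mis18A
C6orf173	1	4	CENPW
CASC5	2	3	KNL1
CCDC99	2	3	Spindly
CDC20	3	7	
CDCA8	2	19	Borealin
CENPA	3	14	
CENPB	3	0	
CENPC1	3	0	
CENPE	3	19	
CENPF	3	11	
CENPH	2	2	
CENPI	3	0	
CENPK	2	3	
CENPL	2	0	
CENPM	2	5	
CENPN	2	0	
CENPO	2	1	
CENPP	2	0	
CENPQ	2	2	
CENPT	2	0	
CENPV	2	0	PRR6
CLASP1	3	1	
CLASP2	3	0	
CLIP1	3	0	
DSN1	2	0	
ERCC6L	2	1	PICH
HJURP	2	9	
INCENP	2	1	
ITGB3BP	3	23	CENPR
KIF2C	3	23	
KNTC1	3	11	Rod
MAD1L1	3	1	
MAD2L1	2	11	
MAD2L1BP	3	2	p31comet
MIS12	2	0	
MLF1IP	2	20	CENPU
NDC80	3	12	
NEK2	3	13	
NSL1	2	1	
NUF2	2	7	
OIP5	3	20	MIS18B
PLK1	3	19	
PMF1	3	0	
RCC2	2	0	TD60
SGOL1	1	2	
SGOL2	1	5	
SKA1	2	4	C18orf24
SKA	2	2	FAM33A
SKA3	2	9	C13orf3
SPC24	2	2	
SPC25	3	15	
STRA13	3	0	CENPX
TTK	3	15	
ZW10	2	6	
ZWILCH	2	6	
ZWINT	3	34	
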