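gene_symbol	occurrences
ZWINT	34
TRIP13	31
BUB1B	30
CCNB2	30
CHEK1	27
KIF14	26
STIL	26
PTTG1	25
RRM1	25
ESPL1	24
NCAPH	24
ITGB3BP	23
KIF2C	23
RACGAP1	22
RFC4	22
FOXM1	21
BUB1	20
CCNB1	20
CKS1B	20
DBF4	20
FANCI	20
MLF1IP	20
NUSAP1	20
OIP5	20
TPX2	20
CDC2	19
CDCA8	19
CENPE	19
HMMR	19
MELK	19
PLK1	19
SMC4	19
TMPO	18
UBE2C	18
CDC45L	17
CDCA3	17
RFC3	17
ASF1B	16
CDKN3	16
KIF11	16
MCM2	16
PPIL5	16
RFC5	16
SPAG5	16
CDC25A	15
CDC6	15
CDCA5	15
PCNA	15
SPC25	15
TTK	15
CDK2	14
CENPA	14
GMPS	14
KIFC1	14
KPNA2	14
PBK	14
SMC2	14
TIMELESS	14
TYMS	14
CKAP2	13
DDX39	13
DTL	13
GMNN	13
MRPL39	13
NEK2	13
PSMG1	13
TTF2	13
WHSC1	13
ABCF1	12
IGF2BP3	12
MCM4	12
NDC80	12
POLE2	12
RNASEH2A	12
SUPT16H	12
UBE2T	12
AK129567	11
CENPF	11
CTPS	11
DLGAP5	11
DUT	11
KNTC1	11
MAD2L1	11
NUP155	11
PAK6	11
CCNA2	10
CDCA7	10
KIF20B	10
MCM3	10
WDR12	10
ARHGAP11A	9
AURKA	9
BLM	9
C13orf3	9
CHTF18	9
EZH2	9
GINS1	9
HJURP	9
MICB	9
NCAPD2	9
NUP107	9
NUP205	9
PAXIP1	9
PKMYT1	9
PPAT	9
TOP2A	9
TROAP	9
TSR1	9
TUBGCP4	9
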