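gene	direction
GREB1	1
PGR	1
TFF1	1
MYB	1
IGFBP4	1
CA12	1
NRIP1	1
SGK3	1
RET	1
CELSR2	1
AREG	1
STC2	1
MYC	1
CCND1	1
PDZK1	1
SLC39A6	1
ABAT	1
KRT19	1
RAPGEF3	1
SIAH2	1
CXCL12	-1
IL1R1	-1
ESR2	-1
TGFB2	-1
CDKN1A	-1
TNFSF10	-1
SMAD6	-1
BCL2L11	-1
EGR1	-1
SOX4	-1
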