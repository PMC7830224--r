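gene	subset1	subset2
ACAN	FALSE	TRUE
ACE	FALSE	TRUE
ADRA1D	FALSE	TRUE
ADRA2A	TRUE	FALSE
ADRA2C	FALSE	TRUE
ADRB2	TRUE	TRUE
AGER	TRUE	FALSE
APOE	TRUE	TRUE
AR	FALSE	TRUE
CALCA	FALSE	TRUE
CASP9	FALSE	TRUE
CCL21	TRUE	FALSE
CCL5	TRUE	FALSE
CCR2	TRUE	FALSE
CCR7	TRUE	FALSE
CD4	TRUE	FALSE
CD40	TRUE	FALSE
CD74	TRUE	FALSE
CFTR	FALSE	TRUE
CHRNA7	TRUE	FALSE
COMT	FALSE	TRUE
CRHBP	FALSE	TRUE
CXCL8	FALSE	TRUE
DRD1	TRUE	FALSE
DRD2	TRUE	TRUE
DRD4	FALSE	TRUE
EDN1	TRUE	FALSE
ESR1	FALSE	TRUE
F2R	TRUE	FALSE
F2RL1	TRUE	FALSE
GCH1	FALSE	TRUE
GDF5	FALSE	TRUE
GSTM1	FALSE	TRUE
HLA-DRB1	FALSE	TRUE
HTR2A	FALSE	TRUE
IFNG	TRUE	FALSE
IL10	FALSE	TRUE
IL1A	FALSE	TRUE
IL1B	TRUE	TRUE
IL1RN	FALSE	TRUE
IL6	TRUE	FALSE
KCNS1	FALSE	TRUE
LYN	TRUE	FALSE
MAOA	FALSE	TRUE
MAPK1	TRUE	FALSE
MC2R	FALSE	TRUE
MTHFD1	FALSE	TRUE
MTRR	FALSE	TRUE
NFKBIA	FALSE	TRUE
NR3C1	FALSE	TRUE
OPRM1	TRUE	TRUE
P2RX7	TRUE	TRUE
PGR	FALSE	TRUE
POMC	FALSE	TRUE
PRKCA	TRUE	FALSE
PRKCD	TRUE	FALSE
PRSS1	FALSE	TRUE
PTGS2	FALSE	TRUE
SCN9A	FALSE	TRUE
SERPINA6	FALSE	TRUE
SHMT1	FALSE	TRUE
SMAD3	FALSE	TRUE
SOD2	FALSE	TRUE
SPINK1	FALSE	TRUE
STAT6	FALSE	TRUE
TGFB1	FALSE	TRUE
TLR4	TRUE	FALSE
TLR9	TRUE	FALSE
TNF	TRUE	TRUE
TRPA1	FALSE	TRUE
TRPM8	FALSE	TRUE
TRPV1	FALSE	TRUE
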