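NPR3
NFE2L1
TNFSF10
HMGB2
GABPB2
KDM5D
RSRP1
GPCPD1
ZNF83
THY1
COX7B
NPPB
PDZK1IP1
BCL6
IRAK3
GRN
SOCS3
CASP5
RPS24
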