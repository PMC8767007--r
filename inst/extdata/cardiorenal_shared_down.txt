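BCL3
ZRANB2
NR1D2
C7
LYN
ANXA3
PER3
PTP4A3
RPLP0
HSPB1
ACTG1
RPL13
HCAR3
FCGR3A
MAP2K3
MYC
CIRBP
AHSA2
ATP1A1
NPIPB3
PNISR
RPS2
ENO1
CNN1
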