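gene_symbol
RAB1A
RAB1B
RAB2A
RAB5A
RAB6A
RAB7A
RAB8A
RAB11A
RAB27A
SEC13
SEC16A
SEC22B
SEC23A
SEC24A
SEC31A
SEC61A1
COPA
COPB1
COPB2
COPG1
COPE
ARF1
ARF4
SAR1A
SAR1B
VAMP2
VAMP3
VAMP7
VAMP8
STX4
STX6
SNAP23
NSF
NAPA
SYT11
CLTA
CLTB
CLTC
AP1B1
AP2A1
AP2M1
DNM2
EEA1
SNX1
SNX2
VPS35
VPS26A
SORT1
M6PR
LAMP1
LAMP2
TMED2
TMED10
GOLGA2
GOLGB1
USO1
STX5
BET1
GOSR1
YKT6
KIF5B
KIF11
DYNC1H1
ACTB
ACTG1
CD74
CD14
CLU
MARCO
MSR1
B2M
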