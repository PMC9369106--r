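gene,role
ADAM17,target
ADAM9,target
ANG,target
ANXA2P2,target
APP,target
AQP1,target
BMPR1A,target
CALD1,target
CD59,target
CLEC2B,target
CLIC4,target
ERBB2,target
FCGR2A,target
GPX1,target
HSPB1,target
ITGA7,target
JAG1,target
LGALS3,target
MEG3,target
NME4,target
NR4A3,target
NRP1,target
PDCL3,target
PSMD7,target
RAC1,target
RBX1,target
RHOA,target
RNH1,target
RPS27A,target
RTN4,target
SDC4,target
TCEB1,target
TLR4,target
TNFRSF1A,target
TNS1,target
TNXB,target
ACTB,reference
B2M,reference
GAPDH,reference
RPL19,reference
RPLP0,reference
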