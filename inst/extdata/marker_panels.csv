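entity,gene,direction,cutoff
NSOI,ANG,up,60
NSOI,AQP1,up,125
NSOI,BMPR1A,up,125
NSOI,CALD1,up,300
NSOI,ERBB2,up,50
NSOI,ITGA7,up,50
NSOI,NME4,up,50
NSOI,NR4A3,up,50
NSOI,PDCL3,up,100
NSOI,TNXB,up,75
NSOI,SDC4,up,100
NSOI,RPS27A,down,5500
MALT,APP,down,400
MALT,AQP1,down,50
MALT,CD59,down,500
MALT,CLIC4,down,200
MALT,HSPB1,down,300
MALT,JAG1,down,50
MALT,LGALS3,down,200
MALT,MEG3,down,75
MALT,NRP1,down,250
MALT,RAC1,down,250
MALT,RTN4,down,250
MALT,TNS1,down,150
IgG4-ROD,ADAM9,up,250
IgG4-ROD,ADAM17,up,300
IgG4-ROD,ANXA2P2,up,3000
IgG4-ROD,CLEC2B,up,500
IgG4-ROD,CLIC4,up,500
IgG4-ROD,FCGR2A,up,500
IgG4-ROD,GPX1,up,600
IgG4-ROD,NRP1,up,1200
IgG4-ROD,PSMD7,up,550
IgG4-ROD,RBX1,up,500
IgG4-ROD,RHOA,up,700
IgG4-ROD,RNH1,up,350
IgG4-ROD,TCEB1,up,450
IgG4-ROD,TLR4,up,450
IgG4-ROD,TNFRSF1A,up,400
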