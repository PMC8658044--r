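experiment,cost_kind,CAPST,DUD-E,GLL&GDD,MUV,NRLiSt_BDB,ULS-UDS
C1,indel [6],0.000002,0.005,0.014,0.490,0.012,0.115
C2,sub [5] [6],0.013,0.145,0.333,0.867,0.104,0.500
C3,indel -,0.004,0.001,0.003,0.327,0.003,0.011
C4,sub - =,0.017,0.186,0.206,1.005,0.024,0.607
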