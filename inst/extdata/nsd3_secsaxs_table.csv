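construct,id,concentration,qmax,qmax_rebinned,rg_reciprocal,rg_direct,dmax,mw_kda
NSD3-PWWP2-SET,1_4,3.8,0.16,0.23,36.7,36.8,139.4,53.1
NSD3-PWWP2-SET,1_3,1.6,0.21,0.23,31.3,31.4,108.0,50.8
NSD3-PWWP2-SET,1_2,1.6,0.13,0.24,34.1,34.2,120.0,48.7
NSD3-PWWP2-SET,1_1,0.6,0.23,0.23,33.2,33.3,112.0,43.7
NSD3-SET-PHD4,2_4,4.3,0.20,0.29,36.2,36.3,134.6,42.8
NSD3-SET-PHD4,2_3,1.6,0.16,0.29,35.8,36.0,138.0,40.2
NSD3-SET-PHD4,2_2,1.6,0.14,0.30,36.7,36.8,137.0,40.2
NSD3-SET-PHD4,2_1,1.0,0.18,0.29,36.5,36.6,132.0,41.9
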