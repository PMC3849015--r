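locus,generation,n_tested,rr,rs,ss
rph1,2,94,28,41,27
rph1,5,94,34,43,17
rph1,10,96,38,45,13
rph1,15,95,35,46,14
rph1,20,96,38,48,8
rph2,2,94,20,52,22
rph2,5,96,5,54,37
rph2,10,92,7,38,45
rph2,15,96,0,28,64
rph2,20,96,0,36,58
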