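genotype1,genotype2,dose,survivors
ss,ss,unselected,6
ss,ss,0.008,1
ss,ss,0.01,0
ss,ss,0.02,1
ss,ss,0.03,0
ss,ss,0.05,0
ss,ss,0.06,0
ss,ss,0.1,0
ss,ss,0.2,0
ss,ss,0.5,0
ss,ss,0.8,0
ss,ss,1,0
ss,ss,2,0
ss,ss,3,0
ss,ss,4,0
sr,ss,unselected,16
sr,ss,0.008,11
sr,ss,0.01,6
sr,ss,0.02,4
sr,ss,0.03,0
sr,ss,0.05,0
sr,ss,0.06,0
sr,ss,0.1,0
sr,ss,0.2,0
sr,ss,0.5,0
sr,ss,0.8,0
sr,ss,1,0
sr,ss,2,0
sr,ss,3,0
sr,ss,4,0
rr,ss,unselected,15
rr,ss,0.008,8
rr,ss,0.01,6
rr,ss,0.02,15
rr,ss,0.03,9
rr,ss,0.05,0
rr,ss,0.06,0
rr,ss,0.1,0
rr,ss,0.2,0
rr,ss,0.5,0
rr,ss,0.8,0
rr,ss,1,0
rr,ss,2,0
rr,ss,3,0
rr,ss,4,0
ss,sr,unselected,8
ss,sr,0.008,4
ss,sr,0.01,2
ss,sr,0.02,2
ss,sr,0.03,0
ss,sr,0.05,0
ss,sr,0.06,0
ss,sr,0.1,0
ss,sr,0.2,0
ss,sr,0.5,0
ss,sr,0.8,0
ss,sr,1,0
ss,sr,2,0
ss,sr,3,0
ss,sr,4,0
sr,sr,unselected,25
sr,sr,0.008,21
sr,sr,0.01,29
sr,sr,0.02,5
sr,sr,0.03,1
sr,sr,0.05,0
sr,sr,0.06,0
sr,sr,0.1,0
sr,sr,0.2,0
sr,sr,0.5,0
sr,sr,0.8,0
sr,sr,1,0
sr,sr,2,0
sr,sr,3,0
sr,sr,4,0
rr,sr,unselected,18
rr,sr,0.008,16
rr,sr,0.01,19
rr,sr,0.02,31
rr,sr,0.03,19
rr,sr,0.05,5
rr,sr,0.06,12
rr,sr,0.1,0
rr,sr,0.2,0
rr,sr,0.5,0
rr,sr,0.8,0
rr,sr,1,0
rr,sr,2,0
rr,sr,3,0
rr,sr,4,0
ss,rr,unselected,3
ss,rr,0.008,0
ss,rr,0.01,2
ss,rr,0.02,1
ss,rr,0.03,1
ss,rr,0.05,7
ss,rr,0.06,2
ss,rr,0.1,0
ss,rr,0.2,0
ss,rr,0.5,0
ss,rr,0.8,0
ss,rr,1,0
ss,rr,2,0
ss,rr,3,0
ss,rr,4,0
sr,rr,unselected,2
sr,rr,0.008,3
sr,rr,0.01,3
sr,rr,0.02,2
sr,rr,0.03,10
sr,rr,0.05,9
sr,rr,0.06,6
sr,rr,0.1,8
sr,rr,0.2,1
sr,rr,0.5,3
sr,rr,0.8,0
sr,rr,1,0
sr,rr,2,0
sr,rr,3,0
sr,rr,4,0
rr,rr,unselected,0
rr,rr,0.008,1
rr,rr,0.01,4
rr,rr,0.02,7
rr,rr,0.03,4
rr,rr,0.05,11
rr,rr,0.06,3
rr,rr,0.1,5
rr,rr,0.2,7
rr,rr,0.5,7
rr,rr,0.8,4
rr,rr,1,3
rr,rr,2,3
rr,rr,3,3
rr,rr,4,1
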