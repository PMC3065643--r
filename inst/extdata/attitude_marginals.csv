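design,statement,score,proportion
RR,Reason,-2,0.18
RR,Reason,-1,0.46
RR,Reason,0,0.25
RR,Reason,1,0.08
RR,Reason,2,0.03
RR,Advantage,-2,0.18
RR,Advantage,-1,0.35
RR,Advantage,0,0.25
RR,Advantage,1,0.16
RR,Advantage,2,0.06
DQ,Reason,-2,0.12
DQ,Reason,-1,0.44
DQ,Reason,0,0.24
DQ,Reason,1,0.15
DQ,Reason,2,0.05
DQ,Advantage,-2,0.16
DQ,Advantage,-1,0.36
DQ,Advantage,0,0.31
DQ,Advantage,1,0.12
DQ,Advantage,2,0.05
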