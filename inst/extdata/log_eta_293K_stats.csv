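line,label,statistic,value,n
A,Based on,Valid groups,76,501
B,Goodness of fit,R2,0.9831,460
C,Deviation,Average,0.07,460
D,Deviation,Standard,0.10,460
E,K-fold cv,K,10,413
F,Goodness of fit,Q2,0.975,413
G,Deviation,Average (cv),0.08,413
H,Deviation,Standard (cv),0.11,413
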