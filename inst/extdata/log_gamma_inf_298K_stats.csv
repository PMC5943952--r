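line,label,statistic,value,n
A,Based on,Valid groups,75,675
B,Goodness of fit,R2,0.9789,634
C,Deviation,Average,0.21,634
D,Deviation,Standard,0.27,634
E,K-fold cv,K,10,616
F,Goodness of fit,Q2,0.9737,616
G,Deviation,Average (cv),0.23,616
H,Deviation,Standard (cv),0.31,616
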