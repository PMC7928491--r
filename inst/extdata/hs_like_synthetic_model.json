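{"states":["C1","C2","O1","O2"],"classes":["closed","closed","open_small","open_small"],"amplitudes_pA":{"closed":0,"open_small":1.35},"Q_per_s":{"C1":[-1250,0,800,450],"C2":[0,-4,2.56,1.44],"O1":[500,1166.66666666667,-1666.66666666667,0],"O2":[142.857142857143,333.333333333333,0,-476.190476190476]}}
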