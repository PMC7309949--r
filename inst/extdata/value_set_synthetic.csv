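dimension,level,decrement
mo,1,0
mo,2,0.040
mo,3,0.095
mo,4,0.220
mo,5,0.260
sc,1,0
sc,2,0.035
sc,3,0.085
sc,4,0.200
sc,5,0.235
ua,1,0
ua,2,0.032
ua,3,0.078
ua,4,0.185
ua,5,0.215
pd,1,0
pd,2,0.045
pd,3,0.105
pd,4,0.245
pd,5,0.285
ad,1,0
ad,2,0.038
ad,3,0.090
ad,4,0.215
ad,5,0.250
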