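analyte,stock_mg_ml
C,5.75
dC,4.40
U,1.20
dU,4.58
I,0.928
G,0.987
dG,0.877
A,1.12
dA,5.75
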