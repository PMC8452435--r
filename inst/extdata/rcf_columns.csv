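target,reference,column_id,f_km
C,G,BEH C18,0.129
C,G,SB-C18,0.121
C,G,XR-ODS,0.128
U,G,BEH C18,0.447
U,G,SB-C18,0.438
U,G,XR-ODS,0.480
dU,G,BEH C18,0.126
dU,G,SB-C18,0.122
dU,G,XR-ODS,0.129
I,G,BEH C18,1.925
I,G,SB-C18,2.002
I,G,XR-ODS,1.876
dG,G,BEH C18,0.636
dG,G,SB-C18,0.684
dG,G,XR-ODS,0.688
dC,G,BEH C18,0.099
dC,G,SB-C18,0.102
dC,G,XR-ODS,0.107
A,G,BEH C18,1.598
A,G,SB-C18,1.594
A,G,XR-ODS,1.491
dA,G,BEH C18,0.107
dA,G,SB-C18,0.109
dA,G,XR-ODS,0.114
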