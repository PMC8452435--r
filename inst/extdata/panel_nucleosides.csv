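name,long_name,role,parent_mz,quant_ion_mz,qual_ion_mz,cone_voltage,collision_energy
A,adenosine,target,267,135,108,38,20
C,cytidine,target,242,109,152,6,12
G,guanosine,internal_reference,282,150,133,20,18
I,inosine,target,267,135,92,40,22
U,uridine,target,243,110,152,20,14
dA,2'-deoxyadenosine,target,250,134,160,34,18
dC,2'-deoxycytidine,target,226,93,135,6,16
dG,2'-deoxyguanosine,target,266,150,133,34,30
dU,2'-deoxyuridine,target,227,184,94,10,12
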