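metabolite,degree
L-Glutamic acid,57
Oxoglutaric acid,53
Adenosine triphosphate (ATP),51
Pyruvic acid,50
NADP,46
CO2,46
NADH,44
O2,40
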