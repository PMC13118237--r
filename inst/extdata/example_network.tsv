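L-Glutamic acid	Oxoglutaric acid
L-Glutamic acid	Pyruvic acid
L-Glutamic acid	NADH
Oxoglutaric acid	CO2
Oxoglutaric acid	NADH
Pyruvic acid	CO2
Pyruvic acid	Adenosine triphosphate (ATP)
NADH	O2
NADP	L-Glutamic acid
Adenosine triphosphate (ATP)	O2
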