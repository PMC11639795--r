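frame	EEL	VDWAALS	EGB	ESURF
1	-10.59	-28.34	29.49	-3.43
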