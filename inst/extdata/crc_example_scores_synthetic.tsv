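antibody_id	gene	mapping_id	score
AB-CEACAM5	CEACAM5	Colorectal-A	200.5
AB-CEACAM6	CEACAM6	Colorectal-A	155.2
AB-ANXA4	ANXA4	Colorectal-A	138.84
AB-CAMP	CAMP	Colorectal-A	132.92
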