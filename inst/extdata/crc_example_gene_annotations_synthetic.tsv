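gene	is_biomarker	is_disease_related
CEACAM5	TRUE	TRUE
CEACAM6	TRUE	TRUE
ANXA4	FALSE	TRUE
CAMP	TRUE	TRUE
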