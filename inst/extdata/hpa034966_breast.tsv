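antibody_id	gene	tissue	cell_type	sample_kind	cancer_type	patient_id	intensity	quantity
HPA034966	EX001	breast	glandular cells	normal			Moderate	>75%
HPA034966	EX001			cancer	Breast cancer	P01	Strong	>75%
HPA034966	EX001			cancer	Breast cancer	P02	Moderate	>75%
HPA034966	EX001			cancer	Breast cancer	P03	Strong	>75%
HPA034966	EX001			cancer	Breast cancer	P04	Strong	>75%
HPA034966	EX001			cancer	Breast cancer	P05	Moderate	>75%
HPA034966	EX001			cancer	Breast cancer	P06	Moderate	>75%
HPA034966	EX001			cancer	Breast cancer	P07	Moderate	>75%
HPA034966	EX001			cancer	Breast cancer	P08	Moderate	>75%
HPA034966	EX001			cancer	Breast cancer	P09	Moderate	>75%
HPA034966	EX001			cancer	Breast cancer	P10	Moderate	>75%
HPA034966	EX001			cancer	Breast cancer	P11	Moderate	>75%
HPA034966	EX001			cancer	Breast cancer	P12	Moderate	>75%
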