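gene	patient_id	fold_change
CEACAM5	P01	7.395
CEACAM5	P02	7.395
CEACAM5	P03	7.395
CEACAM5	P04	7.395
CEACAM5	P05	7.395
CEACAM5	P06	7.395
CEACAM5	P07	7.395
CEACAM5	P08	7.395
CEACAM5	P09	7.395
CEACAM5	P10	7.395
CEACAM5	P11	7.395
CEACAM5	P12	7.395
CEACAM5	P13	7.395
CEACAM5	P14	7.395
CEACAM5	P15	7.395
CEACAM5	P16	7.395
CEACAM5	P17	7.395
CEACAM5	P18	7.395
CEACAM5	P19	7.395
CEACAM5	P20	7.395
CEACAM5	P21	7.395
CEACAM5	P22	7.395
CEACAM5	P23	7.395
CEACAM5	P24	7.395
CEACAM5	P25	0.500
CEACAM5	P26	0.500
CEACAM5	P27	0.500
CEACAM5	P28	0.500
CEACAM6	P01	5.59333333333
CEACAM6	P02	5.59333333333
CEACAM6	P03	5.59333333333
CEACAM6	P04	5.59333333333
CEACAM6	P05	5.59333333333
CEACAM6	P06	5.59333333333
CEACAM6	P07	5.59333333333
CEACAM6	P08	5.59333333333
CEACAM6	P09	5.59333333333
CEACAM6	P10	5.59333333333
CEACAM6	P11	5.59333333333
CEACAM6	P12	5.59333333333
CEACAM6	P13	5.59333333333
CEACAM6	P14	5.59333333333
CEACAM6	P15	5.59333333333
CEACAM6	P16	5.59333333333
CEACAM6	P17	5.59333333333
CEACAM6	P18	5.59333333333
CEACAM6	P19	5.59333333333
CEACAM6	P20	5.59333333333
CEACAM6	P21	5.59333333333
CEACAM6	P22	0.50000000000
CEACAM6	P23	0.50000000000
CEACAM6	P24	0.50000000000
CEACAM6	P25	0.50000000000
CEACAM6	P26	0.50000000000
CEACAM6	P27	0.50000000000
CEACAM6	P28	0.50000000000
ANXA4	P01	3.43066666667
ANXA4	P02	3.43066666667
ANXA4	P03	3.43066666667
ANXA4	P04	3.43066666667
ANXA4	P05	3.43066666667
ANXA4	P06	3.43066666667
ANXA4	P07	3.43066666667
ANXA4	P08	3.43066666667
ANXA4	P09	3.43066666667
ANXA4	P10	3.43066666667
ANXA4	P11	3.43066666667
ANXA4	P12	3.43066666667
ANXA4	P13	3.43066666667
ANXA4	P14	3.43066666667
ANXA4	P15	3.43066666667
ANXA4	P16	0.50000000000
ANXA4	P17	0.50000000000
ANXA4	P18	0.50000000000
ANXA4	P19	0.50000000000
ANXA4	P20	0.50000000000
ANXA4	P21	0.50000000000
ANXA4	P22	0.50000000000
ANXA4	P23	0.50000000000
ANXA4	P24	0.50000000000
ANXA4	P25	0.50000000000
ANXA4	P26	0.50000000000
ANXA4	P27	0.50000000000
ANXA4	P28	0.50000000000
CAMP	P01	5.806
CAMP	P02	5.806
CAMP	P03	5.806
CAMP	P04	5.806
CAMP	P05	5.806
CAMP	P06	5.806
CAMP	P07	5.806
CAMP	P08	5.806
CAMP	P09	5.806
CAMP	P10	5.806
CAMP	P11	5.806
CAMP	P12	5.806
CAMP	P13	5.806
CAMP	P14	5.806
CAMP	P15	5.806
CAMP	P16	5.806
CAMP	P17	5.806
CAMP	P18	5.806
CAMP	P19	5.806
CAMP	P20	5.806
CAMP	P21	0.500
CAMP	P22	0.500
CAMP	P23	0.500
CAMP	P24	0.500
CAMP	P25	0.500
CAMP	P26	0.500
CAMP	P27	0.500
CAMP	P28	0.500
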