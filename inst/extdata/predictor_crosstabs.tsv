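predictor	class	n_neutral	n_non_neutral	n_uncertain
CHASM (breast)	Driver	27	764	1085
CHASM (breast)	Passenger	113	85	1517
CHASM (lung)	Driver	32	783	1155
CHASM (lung)	Passenger	108	66	1447
CHASM (melanoma)	Driver	48	795	1440
CHASM (melanoma)	Passenger	92	54	1162
FATHMM (cancer)	CANCER	71	831	1655
FATHMM (cancer)	PASSENGER/OTHER	69	18	947
FATHMM (missense)	Damaging	69	745	1416
FATHMM (missense)	Tolerated	71	104	1167
FATHMM (missense)	No weights	0	0	19
Mutation Assessor	High	2	71	97
Mutation Assessor	Medium	50	579	1053
Mutation Assessor	Low	51	129	919
Mutation Assessor	Neutral	37	69	527
Mutation Assessor	N/A	0	1	6
MutationTaster	Disease_causing	34	740	1313
MutationTaster	Disease_causing_automatic	1	31	4
MutationTaster	Polymorphism	99	78	1285
MutationTaster	Polymorphism_automatic	6	0	0
PolyPhen-2	Probably damaging	40	600	920
PolyPhen-2	Possibly damaging	26	115	478
PolyPhen-2	Benign	74	134	1204
PROVEAN	Deleterious	43	632	955
PROVEAN	Neutral	97	217	1647
SIFT	Damaging	70	731	1469
SIFT	Tolerated	70	118	1133
VEST	Functional	100	702	1663
VEST	Neutral	40	147	939
CanDrA (breast)	Driver	140	805	2423
CanDrA (breast)	Passenger	0	39	140
CanDrA (breast)	No-call	0	5	39
CanDrA (lung)	Driver	24	767	1150
CanDrA (lung)	Passenger	102	59	1282
CanDrA (lung)	No-call	14	23	170
CanDrA (melanoma)	Driver	28	734	1147
CanDrA (melanoma)	Passenger	97	75	1260
CanDrA (melanoma)	No-call	15	40	195
Condel	Deleterious	77	786	1741
Condel	Neutral	63	63	861
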