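gene	accession	mean_intact_rpkm	mean_irradiated_rpkm	p_value	printed_fold_change
Smedwi-1	DQ186985	275.7	19.3	2.17E-121	-14.28
Smedwi-2	DQ186986	134.7	0.65	1.19E-77	-207.23
Smed-bruli	DQ344977	34.3	19.4	5.29E-03	-1.77
Smed-Histone-H2B	DN290330	50.45	15.1	1.34E-8	-3.34
Smed-nanos-like	EF035555	12.6	0.6	1.71E-07	-21
Dj-PCNA	EU856391	46.85	2.35	9.25E-24	-19.94
Spol-Tudor	FJ655915	49.25	20.65	1.36E-06	-2.38
Smed-HDAC	NP_004955	190.25	94.9	3.65E-15	-2
Smed-NB.21.11.e	FG311845	155.9	0.9	3.64E-89	-173.22
Smed-AGAT-1	AY967547	95.75	0.8	3.2E-45	-118.75
Smed-p53	AY068713	15.0	0.8	1.64E-8	-18.25
Dj-rrm2	AY067447	70.2	8.55	1.34E-26	-8.21
smed-SMB	GU562964	122	36.15	3.05E-23	-3.36
Smed-INX-11	Q851133	50.2	13.4	1.34E-11	-3.75
Dj-Pumilio	AJ639658	72.25	28.55	6.22E-10	-2.53
Dj-EST-H2Az	BP186772	47.55	1.4	5.39E-26	-33.96
DjEST-TAF1-beta	BP187634	584.95	207.15	1.42E-82	-2.82
Smed-CHD4	GU980571	22.15	2.2	3.77E-10	-10.07
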