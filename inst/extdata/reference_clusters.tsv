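term	polarity	structure	hemisphere	ba	volume_ul	com_x	com_y	com_z	crossover
years_use	positive	Precentral Gyrus	L	4	896	-36	-16	62	14.1
years_use	positive	Nodule (Cerebellum)	R	NA	888	4	-42	-38	6.2
years_use	positive	Medial Frontal Gyrus	L	11	392	-2	32	-14	19.5
years_use	positive	Precentral Gyrus	R	6	368	13	-26	73	18.6
years_use	negative	Cerebellar Tonsil	R	NA	1976	39	-56	-53	4.6
years_use	negative	STG/IFG/AI	R	22/13	1360	49	11	-5	2.8
years_use	negative	STG/IFG	L	22/13	1088	-50	13	-7	3.7
years_use	negative	Subcallosal Gyrus	R	34	624	12	1	-17	8.3
years_use	negative	Anterior Cingulate	R	24	448	4	30	14	6.7
abstinence_weeks	positive	Insula	L	13	1512	-37	9	11	29.9
abstinence_weeks	positive	Cuneus	L	31	1480	-26	-79	23	26.4
abstinence_weeks	positive	Superior Frontal Gyrus	L	8	680	-16	46	42	42.3
abstinence_weeks	positive	Culmen	L	NA	648	-14	-48	-12	32.8
abstinence_weeks	positive	Precuneus	R	19	592	31	-78	22	38.0
abstinence_weeks	positive	Cingulate Gyrus	L	32	520	-10	25	31	44.9
abstinence_weeks	positive	Superior Frontal Gyrus	R	10	512	24	54	5	37.1
abstinence_weeks	positive	Cingulate Gyrus	R	31	384	14	-32	41	33.3
abstinence_weeks	negative	Cuneus	R	19	520	12	-81	36	27.6
abstinence_weeks	negative	Precuneus	L	7	488	-4	-62	57	26.6
abstinence_weeks	negative	Culmen of Vermis	L	NA	368	-2	-64	3	18.5
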