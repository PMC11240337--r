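patient_id	age	psa	ipsa	prostate_volume	interval_years	max_pirads	isup_control
P001	75	3.037	3.489	54.69	1.74	3	1
P002	69	15.086	12.41	51.64	1.64	3	2
P003	63	3.798	3.76	47.85	3.74	5	2
P004	68	5.258	7.005	31.49	2.06	4	0
P005	63	15.721	12.925	24.64	0.95	5	2
P006	58	6.68	8.079	72.97	3.32	3	0
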