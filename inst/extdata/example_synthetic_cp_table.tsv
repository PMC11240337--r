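sample_id	assay	cp_rep1	cp_rep2
P001	PPIA	22.093	22.237
P002	PPIA	22.251	22.145
P003	PPIA	24.892	24.766
P004	PPIA	23.322	23.268
P005	PPIA	22.456	22.212
P006	PPIA	22.084	22.205
P001	RPLP0	24.314	24.456
P002	RPLP0	24.334	24.617
P003	RPLP0	24.803	24.75
P004	RPLP0	24.372	24.511
P005	RPLP0	26.963	26.903
P006	RPLP0	26.135	25.942
P001	TBP	26.91	26.879
P002	TBP	25.3	25.28
P003	TBP	27.772	27.688
P004	TBP	25.512	25.598
P005	TBP	27.23	27.361
P006	TBP	28.064	28.03
P001	AMACR	26.454	26.472
P002	AMACR	25.453	25.113
P003	AMACR	28.305	28.496
P004	AMACR	26.113	26.111
P005	AMACR	29.542	29.478
P006	AMACR	26.812	26.662
P001	HPN	29.264	29.419
P002	HPN	27.25	27.177
P003	HPN	29.995	30.236
P004	HPN	27.554	27.547
P005	HPN	29.213	29.196
P006	HPN	29.993	29.831
P001	MALAT1	30.157	30.018
P002	MALAT1	29.447	29.309
P003	MALAT1	30.21	30.058
P004	MALAT1	28.376	28.176
P005	MALAT1	31.135	31.142
P006	MALAT1	30.838	30.578
P001	PCA3	25.83	25.843
P002	PCA3	25.116	24.775
P003	PCA3	27.673	28.115
P004	PCA3	25.341	25.481
P005	PCA3	26.42	26.189
P006	PCA3	25.623	25.882
P001	PCAT29	32.437	32.244
P002	PCAT29	31.263	31.269
P003	PCAT29	34.422	34.563
P004	PCAT29	32.308	32.331
P005	PCAT29	32.716	32.563
P006	PCAT29	34.403	34.123
P001	ERG	29.599	29.917
P002	ERG	29.518	29.764
P003	ERG	32.475	32.471
P004	ERG	31.945	31.922
P005	ERG	32.541	32.696
P006	ERG	31.984	32.263
P001	KLK3	24.702	24.625
P002	KLK3	23.566	23.234
P003	KLK3	25.621	25.818
P004	KLK3	24.214	23.975
P005	KLK3	26.26	26.393
P006	KLK3	25.465	25.589
P001	STAT3	28.963	29.255
P002	STAT3	28.896	29.113
P003	STAT3	31.906	31.829
P004	STAT3	31.213	31.368
P005	STAT3	30.871	30.826
P006	STAT3	30.272	30.183
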