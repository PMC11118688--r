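segment_id	roi_id	subject_id	compartment	arm	raw_reads	aligned_pct	trimmed_pct	stitched_pct	age	sex	grade	stage	tumor_size	margin
T1_R1_carcinoma	T1_R1	T1	carcinoma	naive	150000	79	96	97	62	F	G2	2	3.1	R0
T1_R1_TME	T1_R1	T1	TME	naive	150000	95	96	97	62	F	G2	2	3.1	R0
T1_R2_carcinoma	T1_R2	T1	carcinoma	naive	150000	95	96	97	62	F	G2	2	3.1	R0
T1_R2_TME	T1_R2	T1	TME	naive	150000	95	96	97	62	F	G2	2	3.1	R0
T2_R1_carcinoma	T2_R1	T2	carcinoma	NAT	150000	95	96	97	70	M	G2	2	3.1	R0
T2_R1_TME	T2_R1	T2	TME	NAT	900	95	96	97	70	M	G2	2	3.1	R0
T2_R2_carcinoma	T2_R2	T2	carcinoma	NAT	150000	95	96	97	70	M	G2	2	3.1	R0
T2_R2_TME	T2_R2	T2	TME	NAT	150000	95	96	97	70	M	G2	2	3.1	R0
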