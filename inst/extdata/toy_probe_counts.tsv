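probe_id	gene_symbol	T1_R1_carcinoma	T1_R1_TME	T1_R2_carcinoma	T1_R2_TME	T2_R1_carcinoma	T2_R1_TME	T2_R2_carcinoma	T2_R2_TME
P_G1	G1	51	51	51	51	51	51	2	51
P_G2	G2	52	52	52	52	52	52	2	52
P_G3	G3	53	53	53	53	53	53	2	53
P_G4	G4	54	54	54	54	54	54	2	54
P_G5	G5	55	55	55	55	55	55	2	55
P_G6	G6	56	56	56	56	56	56	2	56
P_G7	G7	57	57	57	57	57	57	2	57
P_G8	G8	58	58	58	58	58	58	2	58
P_G9	G9	59	59	59	59	59	59	2	59
P_GLOW	GLOW	1	1	1	1	1	1	1	1
P_Neg1	NegProbe1	4	4	4	4	4	4	4	4
P_Neg2	NegProbe2	4	4	4	4	4	4	4	4
P_Neg3	NegProbe3	4	4	4	4	4	4	4	4
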