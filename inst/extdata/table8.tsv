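genotype	testis	normal_canoe	abnormal_canoe
Scrambled RNAi	1	2	0
Scrambled RNAi	2	7	1
Scrambled RNAi	3	6	1
Scrambled RNAi	4	3	5
Scrambled RNAi	5	9	1
Scrambled RNAi	6	5	1
AAGAG RNAi	1	1	0
AAGAG RNAi	2	0	1
AAGAG RNAi	3	0	1
AAGAG RNAi	4	1	1
AAGAG RNAi	5	0	0
AAGAG RNAi	6	0	1
AAGAG RNAi	7	0	0
AAGAG RNAi	8	2	4
AAGAG RNAi	9	1	2
AAGAG RNAi	10	0	2
AAGAG RNAi	11	1	2
AAGAG RNAi	12	3	6
AAGAG RNAi	13	2	7
AAGAG RNAi	14	1	5
AAGAG RNA (Rescue)	1	7	4
AAGAG RNA (Rescue)	2	3	2
AAGAG RNA (Rescue)	3	0	3
AAGAG RNA (Rescue)	4	0	4
AAGAG RNA (Rescue)	5	0	3
AAGAG RNA (Rescue)	6	0	0
AAGAG RNA (Rescue)	7	1	4
AAGAG RNA (Rescue)	8	3	4
AAGAG RNA (Rescue)	9	6	8
AAGAG RNA (Rescue)	10	3	3
AAGAG RNA (Rescue)	11	1	0
AAGAG RNA (Rescue)	12	2	2
AAGAG RNA (Rescue)	13	8	9
AAGAG RNA (Rescue)	14	1	6
AAGAG RNA (Rescue)	15	0	2
AAGAG RNA (Rescue)	16	7	9
AAGAG RNA (Rescue)	17	0	1
AAGAG RNA (Rescue)	18	3	2
AAGAG RNA (Rescue)	19	2	4
AAGAG RNA (Rescue)	20	1	1
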