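genotype	testis	normal_bundle	lagging_bundle	kinked	knotted	needle_eyed	decondensed
Scrambled RNAi	1	2	2	4	0	0	0
Scrambled RNAi	2	9	7	6	0	0	0
Scrambled RNAi	3	21	5	0	0	0	0
Scrambled RNAi	4	5	1	0	0	0	0
Scrambled RNAi	5	29	1	0	0	0	0
Scrambled RNAi	6	6	2	0	0	0	0
AAGAG RNAi	1	0	8	2	0	0	2
AAGAG RNAi	2	1	8	0	2	2	0
AAGAG RNAi	3	0	1	5	2	1	0
AAGAG RNAi	4	0	0	1	0	0	0
AAGAG RNAi	5	0	1	2	1	1	0
AAGAG RNAi	6	0	1	5	1	0	0
AAGAG RNAi	7	0	0	3	3	0	0
AAGAG RNAi	8	0	0	0	0	1	0
AAGAG RNAi	9	1	2	4	1	1	0
AAGAG RNAi	10	3	5	2	4	2	0
AAGAG RNAi	11	2	2	14	0	1	0
AAGAG RNAi	12	1	4	9	1	1	0
AAGAG RNA (Rescue)	1	0	1	2	0	0	0
AAGAG RNA (Rescue)	2	5	2	2	0	0	0
AAGAG RNA (Rescue)	3	7	1	1	0	0	0
AAGAG RNA (Rescue)	4	8	3	6	3	0	0
AAGAG RNA (Rescue)	5	0	0	9	0	0	0
AAGAG RNA (Rescue)	6	4	4	6	0	0	0
AAGAG RNA (Rescue)	7	8	4	3	0	0	0
AAGAG RNA (Rescue)	8	9	6	7	0	0	0
AAGAG RNA (Rescue)	9	11	1	5	0	0	0
AAGAG RNA (Rescue)	10	8	2	4	0	0	0
AAGAG RNA (Rescue)	11	3	0	2	0	0	0
AAGAG RNA (Rescue)	12	3	0	6	1	0	0
AAGAG RNA (Rescue)	13	2	2	8	0	0	0
AAGAG RNA (Rescue)	14	5	7	5	0	1	0
AAGAG RNA (Rescue)	15	5	0	3	0	0	0
AAGAG RNA (Rescue)	16	5	5	5	1	0	0
AAGAG RNA (Rescue)	17	3	4	3	0	0	0
AAGAG RNA (Rescue)	18	5	1	6	0	0	0
AAGAG RNA (Rescue)	19	3	11	5	1	0	0
AAGAG RNA (Rescue)	20	3	2	1	0	1	0
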