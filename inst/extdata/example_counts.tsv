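region	resels	subj1	subj2	subj3	subj4	subj5	subj6
IFG_L	6.2	7	4	3	9	15	11
IFG_R	6	1	2	2	1	2	4
STG_L	5.1	9	5	11	9	9	9
STG_R	5.3	0	1	0	0	2	1
Fusiform_L	4	6	7	6	4	3	6
Fusiform_R	4.1	3	1	0	0	1	0
Angular_L	3.6	2	1	2	0	2	3
Angular_R	3.5	1	1	0	2	0	0
rest	62.2	29	47	24	24	16	33
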