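locus	seg_type	total	F	P	ORF
IGH	V	48	11	37	0
IGH	D	17	17	0	0
IGH	J	12	3	1	8
IGH	C	10	8	2	0
IGK	V	28	7	19	2
IGK	J	5	1	0	4
IGK	C	1	1	0	0
IGL	V	125	37	80	8
IGL	J	6	4	0	2
IGL	C	6	3	3	0
TRA	V	305	148	132	25
TRA	J	60	53	2	5
TRA	C	1	1	0	0
TRB	V	153	87	55	11
TRB	D	3	3	0	0
TRB	J	19	15	1	3
TRB	C	3	3	0	0
TRD	V	64	48	12	4
TRD	D	9	6	0	3
TRD	J	4	3	0	1
TRD	C	1	1	0	0
TRG1	V	14	13	1	0
TRG1	J	5	5	0	0
TRG1	C	4	4	0	0
TRG2	V	4	4	0	0
TRG2	J	5	3	0	2
TRG2	C	3	3	0	0
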