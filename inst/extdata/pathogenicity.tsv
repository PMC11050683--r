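mutation	entries	score	call	disease	hit
K659N	2PVY,4J95	0.998	likely pathogenic	UCS	1
N549H	2PWL	0.742	likely pathogenic	CS	1
E565G	2PY3	0.982	likely pathogenic	PS	1
N549T	2PZ5	0.805	likely pathogenic	PS	1
K526E	2PZP	0.967	likely pathogenic	CS	1
K641R	2PZR	0.828	likely pathogenic	PS	1
E565A	2Q0B	0.982	likely pathogenic	PS	1
A628T	3B2T	0.998	likely pathogenic	LADD1	1
K659M	4J96	0.994	likely pathogenic	CC	1
K659E	4J97	0.999	likely pathogenic	EC	1
K659Q	4J98	0.994	likely pathogenic	-	0
K659T	4J99	0.996	likely pathogenic	-	0
R612T	-	0.97	likely pathogenic	LC	1
A648T	-	0.976	likely pathogenic	LADD1	1
G663E	-	0.999	likely pathogenic	PS	1
R678G	-	0.971	likely pathogenic	CS	1
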