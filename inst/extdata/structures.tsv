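entry	n_residues	mutation	region_name	status	disease	chains_removed	removal_note	excluded
1GJO	316	WT	-	Inactive	-	-	-	no
1OEC	316	WT	-	Inactive	-	-	-	no
2PSQ	370	WT	-	Inactive	-	-	-	no
2PVF	334	WT	-	Active	-	-	-	no
3RI1	313	WT	-	Inactive	-	-	-	no
2PVY	324	K659N	Activation Loop	Active	UCS	B,C	2PVYBC removed, Missing residue 659	no
2PWL	324	N549H	Kinase Insert	Active	CS	-	-	no
2PY3	324	E565G	Kinase Insert	Active	PS	-	-	no
2PZ5	324	N549T	Kinase Insert	Active	PS	-	-	no
2PZP	324	K526E	Alpha C helix at N-lobe	Active	CS	-	-	no
2PZR	324	K641R	Kinase Insert	Active	PS	-	-	no
2Q0B	324	E565A	Kinase Insert	Active	PS	-	-	no
3B2T	311	A628T	Catalytic Pocket	Active	LADD1	-	-	no
3CLY	334	C491A	-	Unclear	-	-	-	no
4J95	324	K659N	Activation Loop	Active	UCS	A,D	4J95AD removed, Missing residue 654, 659	no
4J96	324	K659M	Activation Loop	Active	CC	-	-	no
4J97	324	K659E	Activation Loop	Active	EC	-	-	no
4J98	324	K659Q	Activation Loop	Active	-	-	-	no
4J99	324	K659T	Activation Loop	Active	-	A	4J99A removed, Missing residue 653	no
5EG3	334	Multiple	Activation Loop	Active	-	-	-	no
5UGL	324	D650V	Alpha-C tether	Active	-	B	5UGLB removed, Missing residue 659	no
5UGX	324	E565A/D650V	Kinase Hinge/Alpha-C tether	Active	PS	B	5UGXB removed, Missing residue 659	no
5UHN	324	E565A/N549H	Kinase Hinge	Active	PS/CS	B	5UGNB removed, Missing residue 659	no
5UI0	324	E565A/K659M	Kinase Hinge/Activation Loop	Active	PS/CC	-	-	no
6LVK	313	WT	-	Unclear	-	-	-	no
6LVL	313	WT	-	Unclear	-	-	-	no
6V6Q	411	Multiple	-	Intermediate	-	C,D	6V6QCD removed, Missing residue 659	no
7KIA	308	V564F	Gate Keeper	Unclear	-	-	-	no
7KIE	308	V564F	Gate Keeper	Unclear	-	-	-	no
7OZY	NA	-	-	-	-	-	Coordinate file unavailable	yes
8E1X	NA	-	-	-	-	-	Source annotation inconsistent with the deposited structure	yes
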