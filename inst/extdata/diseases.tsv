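class	disease	category	subcategory	mutation	entries
CS	Crouzon Syndrome	Genetic/Development Disorders	Craniofacial Syndromes	R678G	-
CS	Crouzon Syndrome	Genetic/Development Disorders	Craniofacial Syndromes	N549H	2PWL
CS	Crouzon Syndrome	Genetic/Development Disorders	Craniofacial Syndromes	K526E	2PZP
PS	Pfeiffer Syndrome	Genetic/Development Disorders	Craniofacial Syndromes	G663E	-
PS	Pfeiffer Syndrome	Genetic/Development Disorders	Craniofacial Syndromes	E565G	2PY3
PS	Pfeiffer Syndrome	Genetic/Development Disorders	Craniofacial Syndromes	K641R	2PZR
PS	Pfeiffer Syndrome	Genetic/Development Disorders	Craniofacial Syndromes	N549T	2PZ5
PS	Pfeiffer Syndrome	Genetic/Development Disorders	Craniofacial Syndromes	E565A	2Q0B
UCS	Unclassified Craniosynostosis Syndrome	Genetic/Development Disorders	Craniofacial Syndromes	K659N	2PVY,4J95
LADD1	Lacrimo-auriculo-dento-digital Syndrome 1	Genetic/Development Disorders	Syndromes with Multiple System Involvement	A628T	3B2T
LADD1	Lacrimo-auriculo-dento-digital Syndrome 1	Genetic/Development Disorders	Syndromes with Multiple System Involvement	A648T	-
CC	Cervical Cancer	Cancers	Gynecological Cancers	K659M	4J96
EC	Endometrial Cancer	Cancers	Gynecological Cancers	K659E	4J97
LC	Lung Cancer	Cancers	Respiratory System Cancer	R612T	-
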