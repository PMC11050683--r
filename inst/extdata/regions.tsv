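symbol	name	ranges
B	Nucleotide-binding loop	480-490
N	Alpha C helix at the kinase N-lobe	525-539
G	Gate keeper	564
H	Kinase hinge and its vicinity	566-571,549,565
K	Kinase insert	579-599
C	Catalytic pocket	620-630
T	Alpha-C tether	650
A	Activation loop	643-649,651-664
O	Others	-
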