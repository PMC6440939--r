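# Coarse contact log-odds potential over residue classes
# (h hydrophobic, p polar, b basic, a acidic) and Cb-Cb distance bins.
# Negative = favorable. Hand-set to encode the qualitative regularities of
# folded proteins (buried hydrophobic pairing, salt bridges, like-charge
# repulsion); labelled "dope-like" in all outputs, not the published DOPE.
class_a	class_b	bin_0_5	bin_5_6.5	bin_6.5_8
h	h	-0.60	-0.40	-0.20
h	p	0.10	0.05	0.00
h	b	0.30	0.15	0.05
h	a	0.30	0.15	0.05
p	p	-0.05	-0.05	0.00
p	b	0.00	0.00	0.00
p	a	0.00	0.00	0.00
b	b	0.60	0.40	0.20
b	a	-0.45	-0.30	-0.15
a	a	0.60	0.40	0.20
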