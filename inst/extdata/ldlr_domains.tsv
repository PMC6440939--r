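# Approximate LDLR (UniProt P01130-1) domain architecture, precursor
# numbering (21-residue signal peptide). Spans rounded to the annotated
# repeat boundaries; the class-B beta-propeller is kept as one track entry.
domain_name	class	start	end
LA1	classA	25	66
LA2	classA	67	105
LA3	classA	106	143
LA4	classA	147	183
LA5	classA	195	232
LA6	classA	234	272
LA7	classA	273	313
EGF1	EGF	314	352
EGF2	EGF	353	393
propeller	classB	394	712
EGF3	EGF	713	751
O-linked	O-linked	754	788
TM	TM	789	810
cytoplasmic	cytoplasmic	811	860
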