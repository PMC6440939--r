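# Weights for the simplified interpretable ddG estimator (kcal/mol per
# unit of each term). Chosen once so that the disulfide and calcium
# penalties dominate the milder physico-chemical terms, as in class-A
# domain biochemistry; not fitted to any experimental set.
term	value
w_clash	0.25
w_hbond	0.5
w_hydropathy	0.3
w_disulfide	3.5
w_calcium	2.0
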