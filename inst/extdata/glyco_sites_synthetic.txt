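# Synthetic O-glycosylation position list (precursor numbering) for
# pipeline demonstrations and tests. These are NOT curated LDLR sites;
# supply your own literature-derived list for real analyses.
757
760
764
768
771
775
780
784
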