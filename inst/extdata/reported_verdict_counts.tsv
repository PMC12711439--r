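category	count
HGT	230
HGT_recipient_shifted	113
Inconclusive	358
Putative_EGT	13
NoHGT	431
Potential_Contamination	25
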