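donor_group	count
Prokaryotes	776
Fungi	280
Metazoa	60
Viruses	28
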