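modifier	finding_id	anatomy_id
medial	TRAK:0001511	TRAK:0001090
patellar	TRAK:0000229	TRAK:0000053
prepatellar	TRAK:0000225	TRAK:0001054
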