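ambiguous_id	context_id	replacement_id
TRAK:0000211	TRAK:0001396	TRAK:0001461
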