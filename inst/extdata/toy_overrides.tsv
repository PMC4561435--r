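kind	surface	id	to_id
ignore_branch		TRAK:0000513
ignore		TRAK:0001410
remap	joint effusion	TRAK:0001410	TRAK:0001411
add	ruptured	TRAK:0000211
add	meniscal	TRAK:0000045
add	lateral meniscal	TRAK:0001089
add	medial meniscal	TRAK:0001090
add	collaterals	TOY:0000011
add	tib-fib joint	TOY:0000025
add	subluxed	TOY:0000164
add	torn	TOY:0000157
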