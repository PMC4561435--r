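id
TOY:0000167
TRAK:0000656
TRAK:0000362
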