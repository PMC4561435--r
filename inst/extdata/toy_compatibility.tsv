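finding_root	anatomy_root
TOY:0000157	TOY:0000010
TRAK:0000211	TOY:0000010
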