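id	label
PATO:0000386	hard
PATO:0000586	increased size
PATO:0000647	necrotic
PATO:0001625	increased functionality
PATO:0002037	degeneration
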