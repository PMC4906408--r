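label	start	end
stem_5p	6	10
stem_3p	14	18
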