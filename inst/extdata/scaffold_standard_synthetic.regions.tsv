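label	start	end
repeat_anti_repeat	1	16
stem_loop_1	20	33
stem_loop_2	38	47
stem_loop_3	51	66
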