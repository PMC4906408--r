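label	start	end
repeat_anti_repeat	1	24
stem_loop_1	28	41
stem_loop_2	46	55
stem_loop_3	59	74
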