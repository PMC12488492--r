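name	start	end	subject
highfat	1	2	M1
highfat	1	2	M2
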