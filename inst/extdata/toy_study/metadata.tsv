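sampleID	subject	time
M1_t0	M1	0
M1_t0.5	M1	0.5
M1_t1	M1	1
M1_t2	M1	2
M2_t0	M2	0
M2_t0.5	M2	0.5
M2_t1	M2	1
M2_t2	M2	2
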