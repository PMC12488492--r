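sampleID	replicate	value
M1_t0	1	1.1e9
M1_t0	2	0.9e9
M1_t0	3	1.0e9
M1_t0.5	1	2.2e9
M1_t0.5	2	1.8e9
M1_t1	1	4.5e9
M1_t1	2	5.5e9
M1_t2	1	9.0e9
M1_t2	2	1.1e10
M2_t0	1	0.8e9
M2_t0	2	1.2e9
M2_t0.5	1	1.9e9
M2_t0.5	2	2.1e9
M2_t1	1	3.8e9
M2_t1	2	4.2e9
M2_t2	1	8.5e9
M2_t2	2	9.5e9
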