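id	M1_t0	M1_t0.5	M1_t1	M1_t2	M2_t0	M2_t0.5	M2_t1	M2_t2
ASV1	120	340	900	1500	80	260	700	1400
ASV2	60	150	420	600	90	210	500	800
ASV3	20	60	180	400	10	40	120	300
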