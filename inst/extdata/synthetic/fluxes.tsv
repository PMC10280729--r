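reaction_id	direction	value
r1	fwd	2
r2	fwd	2
r3	fwd	0.5
r4	fwd	1
r5	fwd	1
r6	fwd	0.8
r6	bwd	0.3
r7	fwd	0.5
r8	fwd	1
r9	fwd	0.5
r10	fwd	1
r11	fwd	1.5
r12	fwd	1
r13	fwd	0.5
r14	fwd	0.5
r15	fwd	1.5
r16	fwd	0.5
r17	fwd	1.5
r18	fwd	0.5
r19	fwd	2
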