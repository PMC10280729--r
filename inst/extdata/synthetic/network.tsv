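reaction_id	equation	atom_map	reversible
r1	1 S_out -> 1 A	S_out[1] -> A[1]	0
r2	1 A -> 1 B	A[1] -> B[1]	0
r3	1 H -> 1 G + 1 C	H[1,2] -> G[1]+C[1]	0
r4	1 L -> 1 E	L[1] -> E[1]	0
r5	1 B -> 1 J	B[1] -> J[1]	0
r6	1 C -> 1 D	C[1] -> D[1]	1
r7	1 G -> 1 D	G[1] -> D[1]	0
r8	1 D -> 1 L	D[1] -> L[1]	0
r9	1 K -> 1 E	K[1] -> E[1]	0
r10	1 B -> 1 I	B[1] -> I[1]	0
r11	1 E -> 1 P	E[1] -> P[1]	0
r12	1 I + 1 J -> 1 H	I[1]+J[1] -> H[1,2]	0
r13	1 H -> 1 K + 1 M	H[1,2] -> K[1]+M[1]	0
r14	1 M -> 1 Q	M[1] -> Q[1]	0
r15	1 P -> 1 F	P[1] -> F[1]	0
r16	1 Q -> 1 N	Q[1] -> N[1]	0
r17	1 F -> 1 O	F[1] -> O[1]	0
r18	1 N -> 1 O	N[1] -> O[1]	0
r19	1 O -> 	 -> 	0
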