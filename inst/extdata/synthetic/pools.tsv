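metabolite_id	pool_size	n_atoms	is_source
S_out	NA	1	1
A	0.3	1	0
B	0.5	1	0
C	0.6	1	0
D	0.65	1	0
E	1.2	1	0
F	0.6	1	0
G	0.4	1	0
H	0.5	2	0
I	0.6	1	0
J	0.8	1	0
K	2	1	0
L	0.8	1	0
M	1	1	0
N	1	1	0
O	5	1	0
P	0.45	1	0
Q	1.5	1	0
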