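metabolite_id	mass_shift	fraction
S_out	0	0
S_out	1	1
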