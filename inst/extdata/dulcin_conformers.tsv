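id	A	B	C	mu_a	mu_b	mu_c	dE	dE_zpe	dG
I	2787	312	292	4.9	0.9	0.9	0	0	9
II	3068	304	290	5.1	0.8	1.5	21	6	0
III	2832	311	286	0.6	1.4	1.9	399	374	399
IV	2394	339	322	4.6	1.2	1.1	356	414	489
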