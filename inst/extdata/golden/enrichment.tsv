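# group	m	n	M	N	score	fisher_p
hub	2	5	59	600	4.0678	0.0819393
non-hub	2	26	59	600	0.782269	1
non-hierarchical	9	40	59	600	2.28814	0.0281891
regular	6	60	59	600	1.01695	1
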