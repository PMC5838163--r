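chr1	955200	956569	E75	37.4503	.
chr1	1391615	1392948	E120	13.797	.
chr2	353757	355107	E11	6.41182	.
chr2	708420	709800	E49	11.8287	.
chr2	926072	927475	E64	16.8543	.
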