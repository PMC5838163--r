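# se_id	chrom	start	end	n_bins	h_score	class
SE_1	chr1	385200	424800	8	0	non-hierarchical
SE_2	chr1	540200	579800	8	0	non-hierarchical
SE_3	chr1	655200	694800	8	0	non-hierarchical
SE_4	chr1	955200	994800	8	2.64575	hierarchical
SE_5	chr1	1130200	1169800	8	0	non-hierarchical
SE_6	chr1	1295200	1334800	8	0	non-hierarchical
SE_7	chr1	1375200	1414800	8	2.64575	hierarchical
SE_8	chr2	325200	364800	8	2.64575	hierarchical
SE_9	chr2	670200	709800	8	2.64575	hierarchical
SE_10	chr2	805200	844800	8	0	non-hierarchical
SE_11	chr2	920200	959800	8	2.64575	hierarchical
SE_12	chr2	1145200	1184800	8	0	non-hierarchical
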