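chr1	1745000	1750000	chr1	1755000	1760000	pair_1	2.08352
chr1	1365000	1370000	chr1	1390000	1395000	pair_2	9.51018
chr1	920000	925000	chr1	955000	960000	pair_3	8.37584
chr1	1345000	1350000	chr1	1390000	1395000	pair_4	8.08823
chr1	1340000	1345000	chr1	1390000	1395000	pair_5	3.14922
chr1	1335000	1340000	chr1	1390000	1395000	pair_6	5.05736
chr1	885000	890000	chr1	955000	960000	pair_7	2.50783
chr1	955000	960000	chr1	1040000	1045000	pair_8	3.76107
chr1	1390000	1395000	chr1	1480000	1485000	pair_9	7.07183
chr1	955000	960000	chr1	1050000	1055000	pair_10	3.083
chr1	850000	855000	chr1	955000	960000	pair_11	2.01909
chr1	1390000	1395000	chr1	1495000	1500000	pair_12	2.57608
chr1	1280000	1285000	chr1	1390000	1395000	pair_13	4.12294
chr1	1390000	1395000	chr1	1505000	1510000	pair_14	4.12294
chr2	705000	710000	chr2	745000	750000	pair_15	6.17934
chr2	705000	710000	chr2	760000	765000	pair_16	3.60589
chr2	870000	875000	chr2	925000	930000	pair_17	6.51615
chr2	290000	295000	chr2	350000	355000	pair_18	4.95352
chr2	865000	870000	chr2	925000	930000	pair_19	9.54441
chr2	705000	710000	chr2	770000	775000	pair_20	5.4567
chr2	350000	355000	chr2	420000	425000	pair_21	2.01909
chr2	630000	635000	chr2	705000	710000	pair_22	5.08218
chr2	350000	355000	chr2	430000	435000	pair_23	6.02801
chr2	625000	630000	chr2	705000	710000	pair_24	6.51615
chr2	705000	710000	chr2	785000	790000	pair_25	3.22369
chr2	350000	355000	chr2	435000	440000	pair_26	6.02801
chr2	245000	250000	chr2	350000	355000	pair_27	5.50117
chr2	350000	355000	chr2	460000	465000	pair_28	2.95136
chr2	205000	210000	chr2	350000	355000	pair_29	7.00973
chr2	750000	755000	chr2	925000	930000	pair_30	4.66776
chr2	705000	710000	chr2	890000	895000	pair_31	3.42067
chr2	740000	745000	chr2	925000	930000	pair_32	4.84412
chr2	735000	740000	chr2	925000	930000	pair_33	2.9927
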