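# se_id	chrom	start	end	frequency	z
SE_1	chr1	385000	390000	0	0
SE_1	chr1	390000	395000	0	0
SE_1	chr1	395000	400000	0	0
SE_1	chr1	400000	405000	0	0
SE_1	chr1	405000	410000	0	0
SE_1	chr1	410000	415000	0	0
SE_1	chr1	415000	420000	0	0
SE_1	chr1	420000	425000	0	0
SE_2	chr1	540000	545000	0	0
SE_2	chr1	545000	550000	0	0
SE_2	chr1	550000	555000	0	0
SE_2	chr1	555000	560000	0	0
SE_2	chr1	560000	565000	0	0
SE_2	chr1	565000	570000	0	0
SE_2	chr1	570000	575000	0	0
SE_2	chr1	575000	580000	0	0
SE_3	chr1	655000	660000	0	0
SE_3	chr1	660000	665000	0	0
SE_3	chr1	665000	670000	0	0
SE_3	chr1	670000	675000	0	0
SE_3	chr1	675000	680000	0	0
SE_3	chr1	680000	685000	0	0
SE_3	chr1	685000	690000	0	0
SE_3	chr1	690000	695000	0	0
SE_4	chr1	955000	960000	5	2.64575
SE_4	chr1	960000	965000	0	-0.377964
SE_4	chr1	965000	970000	0	-0.377964
SE_4	chr1	970000	975000	0	-0.377964
SE_4	chr1	975000	980000	0	-0.377964
SE_4	chr1	980000	985000	0	-0.377964
SE_4	chr1	985000	990000	0	-0.377964
SE_4	chr1	990000	995000	0	-0.377964
SE_5	chr1	1130000	1135000	0	0
SE_5	chr1	1135000	1140000	0	0
SE_5	chr1	1140000	1145000	0	0
SE_5	chr1	1145000	1150000	0	0
SE_5	chr1	1150000	1155000	0	0
SE_5	chr1	1155000	1160000	0	0
SE_5	chr1	1160000	1165000	0	0
SE_5	chr1	1165000	1170000	0	0
SE_6	chr1	1295000	1300000	0	0
SE_6	chr1	1300000	1305000	0	0
SE_6	chr1	1305000	1310000	0	0
SE_6	chr1	1310000	1315000	0	0
SE_6	chr1	1315000	1320000	0	0
SE_6	chr1	1320000	1325000	0	0
SE_6	chr1	1325000	1330000	0	0
SE_6	chr1	1330000	1335000	0	0
SE_7	chr1	1375000	1380000	0	-0.377964
SE_7	chr1	1380000	1385000	0	-0.377964
SE_7	chr1	1385000	1390000	0	-0.377964
SE_7	chr1	1390000	1395000	8	2.64575
SE_7	chr1	1395000	1400000	0	-0.377964
SE_7	chr1	1400000	1405000	0	-0.377964
SE_7	chr1	1405000	1410000	0	-0.377964
SE_7	chr1	1410000	1415000	0	-0.377964
SE_8	chr2	325000	330000	0	-0.377964
SE_8	chr2	330000	335000	0	-0.377964
SE_8	chr2	335000	340000	0	-0.377964
SE_8	chr2	340000	345000	0	-0.377964
SE_8	chr2	345000	350000	0	-0.377964
SE_8	chr2	350000	355000	7	2.64575
SE_8	chr2	355000	360000	0	-0.377964
SE_8	chr2	360000	365000	0	-0.377964
SE_9	chr2	670000	675000	0	-0.377964
SE_9	chr2	675000	680000	0	-0.377964
SE_9	chr2	680000	685000	0	-0.377964
SE_9	chr2	685000	690000	0	-0.377964
SE_9	chr2	690000	695000	0	-0.377964
SE_9	chr2	695000	700000	0	-0.377964
SE_9	chr2	700000	705000	0	-0.377964
SE_9	chr2	705000	710000	7	2.64575
SE_10	chr2	805000	810000	0	0
SE_10	chr2	810000	815000	0	0
SE_10	chr2	815000	820000	0	0
SE_10	chr2	820000	825000	0	0
SE_10	chr2	825000	830000	0	0
SE_10	chr2	830000	835000	0	0
SE_10	chr2	835000	840000	0	0
SE_10	chr2	840000	845000	0	0
SE_11	chr2	920000	925000	0	-0.377964
SE_11	chr2	925000	930000	5	2.64575
SE_11	chr2	930000	935000	0	-0.377964
SE_11	chr2	935000	940000	0	-0.377964
SE_11	chr2	940000	945000	0	-0.377964
SE_11	chr2	945000	950000	0	-0.377964
SE_11	chr2	950000	955000	0	-0.377964
SE_11	chr2	955000	960000	0	-0.377964
SE_12	chr2	1145000	1150000	0	0
SE_12	chr2	1150000	1155000	0	0
SE_12	chr2	1155000	1160000	0	0
SE_12	chr2	1160000	1165000	0	0
SE_12	chr2	1165000	1170000	0	0
SE_12	chr2	1170000	1175000	0	0
SE_12	chr2	1175000	1180000	0	0
SE_12	chr2	1180000	1185000	0	0
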