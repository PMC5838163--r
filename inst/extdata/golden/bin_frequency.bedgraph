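chr1	850000	855000	1
chr1	885000	890000	1
chr1	920000	925000	1
chr1	955000	960000	5
chr1	1040000	1045000	1
chr1	1050000	1055000	1
chr1	1280000	1285000	1
chr1	1335000	1340000	1
chr1	1340000	1345000	1
chr1	1345000	1350000	1
chr1	1365000	1370000	1
chr1	1390000	1395000	8
chr1	1480000	1485000	1
chr1	1495000	1500000	1
chr1	1505000	1510000	1
chr1	1745000	1750000	1
chr1	1755000	1760000	1
chr2	205000	210000	1
chr2	245000	250000	1
chr2	290000	295000	1
chr2	350000	355000	7
chr2	420000	425000	1
chr2	430000	435000	1
chr2	435000	440000	1
chr2	460000	465000	1
chr2	625000	630000	1
chr2	630000	635000	1
chr2	705000	710000	7
chr2	735000	740000	1
chr2	740000	745000	1
chr2	745000	750000	1
chr2	750000	755000	1
chr2	760000	765000	1
chr2	770000	775000	1
chr2	785000	790000	1
chr2	865000	870000	1
chr2	870000	875000	1
chr2	890000	895000	1
chr2	925000	930000	5
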