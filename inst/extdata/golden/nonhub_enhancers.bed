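chr1	964826	966369	E76	19.2308	.
chr1	974462	975271	E77	24.6093	.
chr1	983933	985186	E78	38.1191	.
chr1	993715	994800	E79	28.5453	.
chr1	1375200	1376723	E117	10.7165	.
chr1	1380572	1382037	E118	10.4417	.
chr1	1386472	1387346	E119	46.0998	.
chr1	1397018	1398462	E121	12.2403	.
chr1	1403208	1404511	E122	14.8334	.
chr1	1408290	1409689	E123	26.999	.
chr1	1413987	1414800	E124	18.4159	.
chr2	325200	326041	E8	29.1899	.
chr2	334552	335433	E9	62.794	.
chr2	344645	345911	E10	26.7783	.
chr2	363745	364800	E12	19.8212	.
chr2	670200	671220	E45	19.9816	.
chr2	679414	680793	E46	16.9267	.
chr2	688975	690239	E47	29.6469	.
chr2	699195	700367	E48	36.9484	.
chr2	920200	921713	E63	13.6678	.
chr2	931518	932420	E65	15.7462	.
chr2	936424	937741	E66	6.23117	.
chr2	942085	942921	E67	21.0878	.
chr2	947735	948713	E68	18.9917	.
chr2	953472	954597	E69	25.3784	.
chr2	958701	959800	E70	17.4521	.
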