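chr1	150694	150944	other
chr1	232384	232634	other
chr1	257344	257594	other
chr1	300522	300772	other
chr1	312350	312600	other
chr1	368473	368723	other
chr1	416334	416584	other
chr1	453016	453266	TAD-boundary
chr1	454900	455100	TAD-boundary
chr1	669307	669557	other
chr1	734960	735210	other
chr1	760097	760347	other
chr1	768276	768526	other
chr1	864900	865100	TAD-boundary
chr1	957350	957650	other
chr1	1108090	1108340	other
chr1	1249900	1250100	TAD-boundary
chr1	1318308	1318558	other
chr1	1319372	1319622	other
chr1	1392350	1392650	hub
chr1	1394640	1394890	other
chr1	1423275	1423525	other
chr1	1529900	1530100	TAD-boundary
chr1	1767888	1768138	other
chr1	1952787	1953037	other
chr1	1966684	1966934	other
chr2	32944	33194	other
chr2	56012	56262	other
chr2	110583	110833	other
chr2	121480	121730	other
chr2	131165	131415	other
chr2	262022	262272	other
chr2	294707	294957	other
chr2	300666	300916	other
chr2	339900	340100	TAD-boundary
chr2	352350	352650	other
chr2	364373	364623	non-hub
chr2	383403	383653	other
chr2	679900	680100	TAD-boundary
chr2	692262	692512	other
chr2	707350	707650	other
chr2	733982	734232	other
chr2	860575	860825	other
chr2	927350	927650	hub
chr2	954900	955100	TAD-boundary
chr2	991504	991754	other
chr2	1279900	1280100	TAD-boundary
chr2	1333776	1334026	other
chr2	1442521	1442771	other
chr2	1499507	1499757	other
chr2	1674900	1675100	TAD-boundary
chr2	1808481	1808731	other
chr2	1855458	1855708	other
chr2	1945909	1946159	other
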