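chr1	1130200	1131113	SE_1_1	27.3173	.
chr1	1135765	1136791	SE_1_2	37.6434	.
chr1	1140895	1141861	SE_1_3	33.3256	.
chr1	1146548	1147447	SE_1_4	21.6904	.
chr1	1152429	1153905	SE_1_5	37.468	.
chr1	1158248	1159422	SE_1_6	7.18607	.
chr1	1163164	1164211	SE_1_7	55.6691	.
chr1	1168982	1169800	SE_1_8	15.2165	.
chr1	1295200	1296293	SE_2_1	32.8518	.
chr1	1300957	1301840	SE_2_2	25.9484	.
chr1	1305911	1306876	SE_2_3	16.7539	.
chr1	1311589	1312411	SE_2_4	14.4498	.
chr1	1317231	1318757	SE_2_5	16.1749	.
chr1	1323232	1324488	SE_2_6	18.3428	.
chr1	1328374	1329388	SE_2_7	34.1536	.
chr1	1333988	1334800	SE_2_8	19.9605	.
chr1	1375200	1376723	SE_3_1	10.7165	.
chr1	1380572	1382037	SE_3_2	10.4417	.
chr1	1386472	1387346	SE_3_3	46.0998	.
chr1	1391615	1392948	SE_3_4	13.797	.
chr1	1397018	1398462	SE_3_5	12.2403	.
chr1	1403208	1404511	SE_3_6	14.8334	.
chr1	1408290	1409689	SE_3_7	26.999	.
chr1	1413987	1414800	SE_3_8	18.4159	.
chr1	955200	956569	SE_4_1	37.4503	.
chr1	964826	966369	SE_4_2	19.2308	.
chr1	974462	975271	SE_4_3	24.6093	.
chr1	983933	985186	SE_4_4	38.1191	.
chr1	993715	994800	SE_4_5	28.5453	.
chr2	325200	326041	SE_5_1	29.1899	.
chr2	334552	335433	SE_5_2	62.794	.
chr2	344645	345911	SE_5_3	26.7783	.
chr2	353757	355107	SE_5_4	6.41182	.
chr2	363745	364800	SE_5_5	19.8212	.
chr2	920200	921713	SE_6_1	13.6678	.
chr2	926072	927475	SE_6_2	16.8543	.
chr2	931518	932420	SE_6_3	15.7462	.
chr2	936424	937741	SE_6_4	6.23117	.
chr2	942085	942921	SE_6_5	21.0878	.
chr2	947735	948713	SE_6_6	18.9917	.
chr2	953472	954597	SE_6_7	25.3784	.
chr2	958701	959800	SE_6_8	17.4521	.
chr1	385200	386666	SE_7_1	9.78996	.
chr1	392820	393653	SE_7_2	8.17488	.
chr1	400682	402102	SE_7_3	28.7423	.
chr1	408058	408966	SE_7_4	11.8448	.
chr1	415809	416913	SE_7_5	54.3268	.
chr1	423480	424800	SE_7_6	16.9797	.
chr2	1145200	1146242	SE_8_1	25.6489	.
chr2	1154990	1156359	SE_8_2	37.891	.
chr2	1164053	1165216	SE_8_3	7.38751	.
chr2	1173771	1174939	SE_8_4	34.3502	.
chr2	1183269	1184800	SE_8_5	17.9601	.
chr1	540200	541084	SE_9_1	37.6012	.
chr1	553386	554277	SE_9_2	22.0875	.
chr1	566162	567034	SE_9_3	19.7554	.
chr1	578746	579800	SE_9_4	37.2587	.
chr2	670200	671220	SE_10_1	19.9816	.
chr2	679414	680793	SE_10_2	16.9267	.
chr2	688975	690239	SE_10_3	29.6469	.
chr2	699195	700367	SE_10_4	36.9484	.
chr2	708420	709800	SE_10_5	11.8287	.
chr1	655200	656618	SE_11_1	37.0216	.
chr1	668228	669653	SE_11_2	26.6075	.
chr1	680597	682121	SE_11_3	15.5472	.
chr1	693390	694800	SE_11_4	32.9416	.
chr2	805200	806342	SE_12_1	12.3528	.
chr2	814664	815632	SE_12_2	29.7127	.
chr2	824114	825478	SE_12_3	19.7285	.
chr2	833938	835027	SE_12_4	25.1262	.
chr2	843668	844800	SE_12_5	9.52153	.
chr2	526431	527662	RE_13_1	6.41101	.
chr1	927645	928809	RE_14_1	5.54662	.
chr1	471948	473168	RE_15_1	5.54309	.
chr1	1038093	1039244	RE_16_1	5.48232	.
chr2	889162	890388	RE_17_1	5.09329	.
chr1	517503	518141	RE_18_1	4.24486	.
chr2	547137	548604	RE_19_1	4.01555	.
chr2	1034902	1035664	RE_20_1	3.82954	.
chr1	861829	862826	RE_21_1	3.79649	.
chr1	843308	844125	RE_22_1	3.53423	.
chr1	1517063	1518060	RE_23_1	3.04808	.
chr2	1301289	1302060	RE_24_1	3.01014	.
chr2	606003	607377	RE_25_1	2.97948	.
chr1	497250	498384	RE_26_1	2.86609	.
chr1	789863	791230	RE_27_1	2.81912	.
chr2	636500	637231	RE_28_1	2.70327	.
chr2	1007069	1008384	RE_29_1	2.63637	.
chr2	1370963	1371873	RE_30_1	2.5969	.
chr2	1398380	1399055	RE_31_1	2.53183	.
chr2	1104021	1105517	RE_32_1	2.53002	.
chr1	1215680	1216900	RE_33_1	2.47924	.
chr1	741351	742550	RE_34_1	2.45759	.
chr2	457136	457856	RE_35_1	2.44547	.
chr1	1238330	1239635	RE_36_1	2.341	.
chr1	294105	295450	RE_37_1	2.2881	.
chr2	1121039	1121961	RE_38_1	2.27321	.
chr1	1101581	1103044	RE_39_1	2.16607	.
chr1	1488307	1489365	RE_40_1	2.11072	.
chr1	1057309	1058119	RE_41_1	2.04309	.
chr2	432395	433225	RE_42_1	2.02219	.
chr2	477125	478222	RE_43_1	1.99336	.
chr1	1269372	1270555	RE_44_1	1.92902	.
chr2	578350	579045	RE_45_1	1.91916	.
chr2	1270402	1271884	RE_46_1	1.85631	.
chr2	1058447	1059130	RE_47_1	1.85364	.
chr2	1419253	1420161	RE_48_1	1.84283	.
chr2	1246327	1247621	RE_49_1	1.82519	.
chr1	336509	337922	RE_50_1	1.72845	.
chr2	1228012	1228796	RE_51_1	1.6664	.
chr2	268918	270201	RE_52_1	1.65572	.
chr1	624329	625071	RE_53_1	1.63607	.
chr1	765334	766078	RE_54_1	1.61375	.
chr1	879095	879976	RE_55_1	1.58536	.
chr2	1327564	1328533	RE_56_1	1.56567	.
chr2	403390	404528	RE_57_1	1.4042	.
chr1	271439	272668	RE_58_1	1.38861	.
chr2	504964	505727	RE_59_1	1.35491	.
chr2	1349016	1349874	RE_60_1	1.33302	.
chr1	900311	901576	RE_61_1	1.25531	.
chr2	757761	758763	RE_62_1	1.25526	.
chr1	1081451	1082222	RE_63_1	1.22719	.
chr2	292936	294202	RE_64_1	1.22346	.
chr1	363652	364913	RE_65_1	1.2004	.
chr1	816386	817137	RE_66_1	1.11899	.
chr1	250000	250675	RE_67_1	1.09756	.
chr2	775331	776200	RE_68_1	1.09711	.
chr2	1085923	1086907	RE_69_1	0.980648	.
chr2	250000	251168	RE_70_1	0.969474	.
chr1	317368	318619	RE_71_1	0.802436	.
chr1	1460099	1461493	RE_72_1	0.799509	.
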