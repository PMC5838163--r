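chr1	1130200	1169800	SE_1	235.516	.
chr1	1295200	1334800	SE_2	178.636	.
chr1	1375200	1414800	SE_3	153.544	.
chr1	955200	994800	SE_4	147.955	.
chr2	325200	364800	SE_5	144.995	.
chr2	920200	959800	SE_6	135.409	.
chr1	385200	424800	SE_7	129.858	.
chr2	1145200	1184800	SE_8	123.238	.
chr1	540200	579800	SE_9	116.703	.
chr2	670200	709800	SE_10	115.332	.
chr1	655200	694800	SE_11	112.118	.
chr2	805200	844800	SE_12	96.4417	.
chr2	526431	527662	RE_13	6.41101	.
chr1	927645	928809	RE_14	5.54662	.
chr1	471948	473168	RE_15	5.54309	.
chr1	1038093	1039244	RE_16	5.48232	.
chr2	889162	890388	RE_17	5.09329	.
chr1	517503	518141	RE_18	4.24486	.
chr2	547137	548604	RE_19	4.01555	.
chr2	1034902	1035664	RE_20	3.82954	.
chr1	861829	862826	RE_21	3.79649	.
chr1	843308	844125	RE_22	3.53423	.
chr1	1517063	1518060	RE_23	3.04808	.
chr2	1301289	1302060	RE_24	3.01014	.
chr2	606003	607377	RE_25	2.97948	.
chr1	497250	498384	RE_26	2.86609	.
chr1	789863	791230	RE_27	2.81912	.
chr2	636500	637231	RE_28	2.70327	.
chr2	1007069	1008384	RE_29	2.63637	.
chr2	1370963	1371873	RE_30	2.5969	.
chr2	1398380	1399055	RE_31	2.53183	.
chr2	1104021	1105517	RE_32	2.53002	.
chr1	1215680	1216900	RE_33	2.47924	.
chr1	741351	742550	RE_34	2.45759	.
chr2	457136	457856	RE_35	2.44547	.
chr1	1238330	1239635	RE_36	2.341	.
chr1	294105	295450	RE_37	2.2881	.
chr2	1121039	1121961	RE_38	2.27321	.
chr1	1101581	1103044	RE_39	2.16607	.
chr1	1488307	1489365	RE_40	2.11072	.
chr1	1057309	1058119	RE_41	2.04309	.
chr2	432395	433225	RE_42	2.02219	.
chr2	477125	478222	RE_43	1.99336	.
chr1	1269372	1270555	RE_44	1.92902	.
chr2	578350	579045	RE_45	1.91916	.
chr2	1270402	1271884	RE_46	1.85631	.
chr2	1058447	1059130	RE_47	1.85364	.
chr2	1419253	1420161	RE_48	1.84283	.
chr2	1246327	1247621	RE_49	1.82519	.
chr1	336509	337922	RE_50	1.72845	.
chr2	1228012	1228796	RE_51	1.6664	.
chr2	268918	270201	RE_52	1.65572	.
chr1	624329	625071	RE_53	1.63607	.
chr1	765334	766078	RE_54	1.61375	.
chr1	879095	879976	RE_55	1.58536	.
chr2	1327564	1328533	RE_56	1.56567	.
chr2	403390	404528	RE_57	1.4042	.
chr1	271439	272668	RE_58	1.38861	.
chr2	504964	505727	RE_59	1.35491	.
chr2	1349016	1349874	RE_60	1.33302	.
chr1	900311	901576	RE_61	1.25531	.
chr2	757761	758763	RE_62	1.25526	.
chr1	1081451	1082222	RE_63	1.22719	.
chr2	292936	294202	RE_64	1.22346	.
chr1	363652	364913	RE_65	1.2004	.
chr1	816386	817137	RE_66	1.11899	.
chr1	250000	250675	RE_67	1.09756	.
chr2	775331	776200	RE_68	1.09711	.
chr2	1085923	1086907	RE_69	0.980648	.
chr2	250000	251168	RE_70	0.969474	.
chr1	317368	318619	RE_71	0.802436	.
chr1	1460099	1461493	RE_72	0.799509	.
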