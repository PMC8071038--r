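Measure:volume	Left-Thalamus-Proper	Left-Caudate	Left-Putamen	Left-Pallidum	Right-Thalamus-Proper	Right-Caudate	Right-Putamen	Right-Pallidum	Brain-Stem	CSF	lhCortexVol	rhCortexVol	lhCerebralWhiteMatterVol	rhCerebralWhiteMatterVol	TotalGrayVol	BrainSegVolNotVent
case_0001	1334.9460897279409	981.74445868881776	1333.6872077165046	1530.6617029677211	2316.8919318601179	2191.98751100136	3136.0251813100467	1956.5566743566965	2240.5319563295484	2626.3339270024589	1046.2438510941777	1175.1253739282856	1314.8922582984048	2980.9633157499975	1493.7308988326492	158041.98683810406
case_0002	1202.4421651175153	1851.3642739818345	1134.111998948704	1032.8378137510051	2349.9108208849475	3274.0238425663883	2531.0640209360786	1832.8388059435017	1558.6746917765827	3486.3587415898414	1096.663237722003	1457.1138588734975	1276.5939998946203	3668.7258697298148	3409.2784191583314	160489.57778410724
case_0003	1069.4085469529541	1231.2800375722991	1065.4343083058229	1345.3550771714329	2553.7092737541093	2167.7960039579452	2774.4936437125448	1109.2699124537824	2271.9947952252387	2189.9766366424583	1174.4437701002473	1328.067603327263	1497.2460190916072	3971.0898938076052	2724.9391226860171	162575.40799633742
case_0004	921.2618829823972	1419.6795240297636	973.82254425934002	1065.9373499138524	1798.1552510206664	2953.3787007682467	2939.0203514114014	1809.5425739316081	2691.0176687672406	2779.8888500239063	1554.7615145050256	2193.1511558885668	1830.8719837364895	4710.1284182508143	2590.2006744520509	162809.65479866849
case_0005	1723.3766333897129	2714.0779549504064	1197.1094224281501	1411.5418253705907	2482.6998520419024	3584.4396716665638	3539.1868272348374	1544.3693734659707	2084.4470903430415	3855.8714328222386	1130.7082721791855	1668.0537846603572	1099.0963522085437	4309.4014161372952	2430.8770868531979	161716.7657258015
case_0006	1075.3589153922958	1490.318513152047	1173.532745825903	1096.5089906698811	1896.2752288095301	2302.7250417869805	3098.0871617495491	1265.4767976700928	1791.5237475134909	2288.5434458131549	1058.864109866128	982.35266419981406	1162.4470006849649	3359.9301794450616	2385.0170331088075	154433.66005070158
case_0007	1487.1912005361828	1468.3950745056013	1301.3613375333807	1298.7289921610734	2143.5403065314426	2973.4875944164014	3044.6157538255461	1493.9643313301826	2178.1610062445616	2692.4077527445279	831.66238238177868	878.6994529838779	1240.5902648396241	4179.6828556588725	2142.9456465884268	161847.37139075631
case_0008	1429.0853007423841	1334.0799634445277	1220.571536499828	1337.4785866614955	2517.1615455279548	3190.2680664059899	2773.8840185920653	2021.6284384621385	1948.6074118966021	3576.892307847444	1003.7258488042112	936.73328194047428	1464.2971928641048	2901.1685030673302	2818.7757176205132	161407.90672155417
control_0001	1089.2073808697319	1233.1057106526086	1019.6819681007937	1031.4298838643824	1719.2574706031223	1996.3821992818007	2670.4591603281569	2014.4557539593188	2583.0252181121955	2203.0540676431438	1187.1445466569139	1394.0670241878911	1367.7468984134732	3495.9565288846456	3236.5910133194388	161994.70112531414
control_0002	804.22522047510301	1374.8731177012135	951.47573863973491	1172.2406931397018	1605.9259622827055	2038.4886381854321	2755.7259808245185	1110.8501846134136	2370.9633858186212	1957.3380007658664	1233.4685269571787	1405.8512236555421	1312.1490791698288	4902.9478755878463	2785.7892240400161	161063.88627905693
control_0003	1414.6729906424757	1194.0180727865047	948.28252237051754	1081.6139247023109	2149.0737370805568	2819.1610216088188	2707.021607092161	972.56882774810913	2100.5323978800534	1459.6460480367941	975.76059403758268	1400.4618776128818	1554.3233892523654	3919.1074218153753	2065.4586826246914	165652.21163316735
control_0004	1015.8122943169569	1063.50126165345	1098.3498659326888	891.58203419427173	1931.6599142911064	2856.9986861075922	3139.6911749869087	1883.32067484818	2016.0904170752883	3414.5073571975126	1046.5817201754667	1405.2066680693288	1775.5888975761068	3575.8716760535372	3156.4912194608887	168161.09201071618
control_0005	1114.1647882162595	1387.9122727520025	972.20285822456526	992.5800107488767	2432.3808889182105	2584.9231294307301	2662.4491774554572	1295.1056045658286	2636.4134884840573	2058.52083414359	1032.0584153615484	598.36305847156552	1484.255590765252	3021.128793784409	2068.4601029975352	161362.67247033128
control_0006	1955.4917855179033	1485.6865889461146	1088.0108309665529	1683.2554581704637	2033.1878025140265	2730.8433710395238	2610.999641765377	1836.3472610885351	2428.4567654729963	4162.6306829033801	1235.9833737682486	2390.5002988761312	1410.7686359829393	4780.2928671175086	3550.5855244458521	166028.93606932653
control_0007	1456.8507625554819	1615.1928229865448	915.25288233423601	1013.1305062108091	3209.3715409037395	4528.8395352503203	3179.1296221922589	1999.4774468772277	2742.1458748241857	2762.7995526101763	1389.5394810520893	936.41222409248951	1756.969748708442	2831.7097869597037	2148.8777518269712	158077.30013540614
control_0008	1236.0994943179894	1855.6765957175096	1251.4935302771351	1244.3039749014245	2574.8965781202169	3048.6749505127132	2434.8983985361133	1507.352503395296	1775.7302176106875	3091.0653553279508	849.59772009973415	678.91264290071854	1052.5223385908353	2682.2616552208401	3014.7162941975275	162757.32772511529
control_0009	1146.1682192597773	1147.2371978247081	972.61535923800579	907.46075976510372	3244.6455372160303	2399.5326634009189	2367.9306393517295	1310.6191098342078	1966.7305009162194	1669.7027912599085	1348.8751217268796	753.53993999309694	1832.9239714972312	3650.1782866836206	3170.6331661388281	160030.60000806974
control_0010	689.00429010823893	1305.2487375091791	1038.8651610049012	1431.4145525545373	2155.8917042613984	2755.971594606498	2932.2729269251649	1439.5607778924775	2897.3091953382659	3726.2780885098687	1214.6968475387055	1063.9977171044618	1235.2270692271586	3908.5730510842263	1722.6732022311151	156664.57969110302
control_0011	1064.1161489384583	1541.9754032697908	1197.8141320128391	1472.892561829779	1582.2480239988199	2343.9875274528817	2968.7873874219695	1232.6393743068334	2372.3114700341962	3313.712771559573	981.81510812467695	978.23698737953737	1040.4912253146231	2832.259840994433	1902.082027761578	158829.05419761973
control_0012	1637.9719681743866	2189.7010403451472	1039.8740053149511	1232.5966451926456	2804.5611520890002	3225.4479531142265	2491.5540470615024	1822.3355500772407	2064.0553826880118	2752.1187222391768	1128.8826329752944	940.24898562968167	1581.7380377219999	3218.9458449998851	2930.1055157339938	170514.101551867
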