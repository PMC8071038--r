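lh.aparc.area	lh_caudalanteriorcingulate_area	lh_caudalmiddlefrontal_area	lh_cuneus_area
case_0001	799.64713897136187	469.11419969221629	725.99557589590802
case_0002	978.29328226934797	1065.4269592710823	901.67114487630829
case_0003	1087.5024043941494	642.87207565681763	875.45217598315105
case_0004	1009.4474646610677	649.52501736942634	602.37281032020712
case_0005	1030.9989244544613	756.65577605465774	941.36892432380171
case_0006	687.55188916781833	653.10863033151782	899.96512829302276
case_0007	620.98074236776472	579.40464898430923	1128.4153766339057
case_0008	1132.4173251830887	659.39131334216313	1003.4858115575029
control_0001	941.59611111702873	604.743844069278	810.09918770976287
control_0002	1071.6025092265868	522.86657240799411	1000.3092917695177
control_0003	830.91290822243889	793.68047188907133	1116.0940569785098
control_0004	1164.9875099694702	966.59607678240945	1379.2926717634621
control_0005	944.55861893506244	864.00375329796202	978.58438201937543
control_0006	1008.048256337321	640.0363663050714	897.92868464430387
control_0007	923.30692800489396	992.34458545121163	620.90343949080284
control_0008	1212.4472093279337	868.07195610880535	1385.1231846091443
control_0009	1024.7101932480289	532.98774083098954	599.31037383864339
control_0010	519.25620496857982	744.90546927722153	578.22703519719096
control_0011	713.74524091336093	572.65866367051524	949.22279405956726
control_0012	1338.7853032104656	1507.2858577778877	1376.2708960646339
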