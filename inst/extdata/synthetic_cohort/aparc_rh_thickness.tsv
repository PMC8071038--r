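rh.aparc.thickness	rh_caudalanteriorcingulate_thickness	rh_caudalmiddlefrontal_thickness	rh_cuneus_thickness	rh_MeanThickness_thickness
case_0001	2.0774173448804771	1.980130307886566	2.9158250317033461	2.5230997235784915
case_0002	2.2669822831840167	2.0800013791471605	2.6517183275433944	2.5503906313564637
case_0003	2.7204914574562826	2.2504806205761825	3.0367792645723903	2.514582509679566
case_0004	2.2399899576316131	1.7705852140146809	2.49376817064261	2.6235546628345117
case_0005	2.5330075506499092	2.0807663486416499	2.9012568084897015	2.56641460904383
case_0006	2.0614520140540815	2.0372052260812827	2.6923274941809532	2.5149384363806604
case_0007	2.2340808680228745	2.179406401382439	2.8849683886914503	2.5051989021737926
case_0008	2.3714462953663347	2.0680998241804023	2.8298353726130854	2.526412974827978
control_0001	2.1496685812562739	1.927156817386215	2.543147064365614	2.5582910468990181
control_0002	2.3118602950649842	1.9584539247558588	2.4871484277856881	2.544875083587228
control_0003	2.3872281237832809	1.9927775028649064	2.9064913249997457	2.5381270844792279
control_0004	2.3771887555907774	2.2243193390517368	3.1872199077971022	2.5757825031087176
control_0005	2.2794490677101917	2.3842062534310333	2.8503388862544567	2.484508869971557
control_0006	2.3836074548275152	2.166293376486391	2.8873670435492151	2.5987145313868965
control_0007	2.1519245037501573	2.3030325641108549	2.7983548861264391	2.4969814356740292
control_0008	2.5177600798628497	2.3743721772667143	3.189319630776724	2.5203903451227756
control_0009	2.3797533498870878	2.2293665572304424	3.2728625850330739	2.5119474675509545
control_0010	2.1093617822942456	1.8922300934234517	2.8891354343424864	2.5123069958140647
control_0011	2.3107480516563599	1.8715956875874145	2.5244367155842804	2.5373622064020847
control_0012	2.5990758015156552	2.3494555316807322	2.7926934004039876	2.5199311207958917
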