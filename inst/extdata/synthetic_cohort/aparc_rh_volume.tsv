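rh.aparc.volume	rh_caudalanteriorcingulate_volume	rh_caudalmiddlefrontal_volume	rh_cuneus_volume
case_0001	1138.322541909781	4017.3555416393651	3052.1841111395638
case_0002	1326.4787407435244	3040.4250960281929	2626.3834667039159
case_0003	1875.2326277718976	3476.6966505025766	5507.3774784072784
case_0004	1214.6818005494977	1977.8502202057325	2388.0350589736518
case_0005	1389.3403783081731	3153.8845871799836	2944.191275670677
case_0006	931.78709303332107	2796.9180057909944	3399.825879215668
case_0007	949.3059907588588	2845.7489319325955	2880.5860836204838
case_0008	1167.4768490999656	3467.529922928923	3425.8510037277665
control_0001	1174.8111223500641	2557.2338503107731	3125.7988643131202
control_0002	1467.0894354718005	2355.648511091108	3052.5479635429911
control_0003	1786.9608304244434	2613.9861365907268	3336.6129334740504
control_0004	1096.3865550680341	2690.8733273224939	3508.9479204909057
control_0005	1092.2827435921974	3211.9010009714534	3988.2655247760426
control_0006	1186.9582252505729	2954.2867730772773	3694.5035677101973
control_0007	1346.5549719987455	3831.5928893869109	3335.8625544577831
control_0008	1617.0772608217005	4106.6766422670862	4388.713890576917
control_0009	1356.7984058304814	4638.8756509366949	4036.9005194807587
control_0010	962.72955417133937	2646.0562376685457	2904.1593477817496
control_0011	1282.565443311272	2146.7541063908866	3189.9492483198187
control_0012	1480.1297049289681	4123.5910728294784	2680.9467283367399
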