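rh.aparc.area	rh_caudalanteriorcingulate_area	rh_caudalmiddlefrontal_area	rh_cuneus_area
case_0001	868.61648489312688	652.33116036171066	558.37449489022015
case_0002	816.56357948629045	779.12280539709229	617.34451876597336
case_0003	1618.7672318194286	704.78927296888787	690.7069269356524
case_0004	700.60259175149827	346.02545735824282	591.44661494109516
case_0005	1078.9062743912161	603.42446987705785	615.95867826462586
case_0006	623.84652447407973	680.96863656928736	681.90221763025522
case_0007	1096.7987842438379	876.3154101525538	779.04261117736201
case_0008	730.020237364992	990.24936837315022	674.66653089688157
control_0001	635.84026042427047	632.86490875509196	528.63256693571827
control_0002	1061.9084007522999	427.52353181731434	574.87951738563936
control_0003	1136.8641118855646	752.57425504745163	702.24730038950395
control_0004	980.97176913051953	1038.1243173840237	883.43279524875402
control_0005	840.20163799943577	1008.1434283183339	690.30847486113873
control_0006	1059.0033548702786	657.82250787228941	598.01675481693542
control_0007	824.11292937780547	836.8518118615342	624.53970226053661
control_0008	1492.1000451655736	971.79159305826977	857.25358696603143
control_0009	1171.9590100061102	756.88574904559744	760.54680012595475
control_0010	707.53886361850016	543.49497838038349	564.06074531249249
control_0011	782.6445846017765	660.65262632938038	680.36301973643617
control_0012	1050.9771228296245	966.15280889356927	666.37429585955658
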