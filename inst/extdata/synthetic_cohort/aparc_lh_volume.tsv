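lh.aparc.volume	lh_caudalanteriorcingulate_volume	lh_caudalmiddlefrontal_volume	lh_cuneus_volume
case_0001	2572.2377970262633	1435.8965715158492	2400.0329229232898
case_0002	3430.4628029412133	2711.5975061607992	2461.9063041240997
case_0003	3466.547173270606	1246.1840567455783	2870.1718139788945
case_0004	3015.7906074612997	1686.0400421633992	2219.431226613387
case_0005	3235.4811580983633	1536.3351715904014	2874.3616215970496
case_0006	2529.2145594926274	1692.5725931815875	2198.8816239228991
case_0007	2894.329174647381	1279.2405972287004	2510.7916458643072
case_0008	3451.1821829538399	1755.0423661291031	2452.0006404225223
control_0001	3750.3137974968458	1966.1581511151646	2238.5765439631255
control_0002	2745.5463977119375	1359.2627001814385	2310.2367116879605
control_0003	2998.4612459500117	2244.5845259098801	2287.8469620943956
control_0004	3319.9411161459252	2297.758642578031	2819.4520991483223
control_0005	3005.9676628937732	2044.3420280906264	2189.6230235819075
control_0006	2820.8872931978822	1600.6343405785281	2588.2490648922194
control_0007	2719.2954204422117	1838.1286231867209	1847.3397150553108
control_0008	3157.5447840863872	1951.8984478103582	2665.9869454862037
control_0009	3177.9076233230994	1161.8382859611324	2146.7667004788727
control_0010	2310.7908450682689	1747.4987329362395	2340.9980195659755
control_0011	2601.295699462421	828.34415348435459	2249.6081001798511
control_0012	3947.0622619231644	2986.0502746888405	2683.7778289014095
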