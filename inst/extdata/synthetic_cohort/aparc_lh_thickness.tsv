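lh.aparc.thickness	lh_caudalanteriorcingulate_thickness	lh_caudalmiddlefrontal_thickness	lh_cuneus_thickness	lh_MeanThickness_thickness
case_0001	2.6503762481411459	2.0038955408129362	1.9261432897187774	2.228699655952183
case_0002	2.9131155317847552	2.513262796265002	2.2133291174558711	2.2123218149204331
case_0003	2.9847806164039725	2.3623283566194178	2.3489337421797254	2.2305286272121072
case_0004	2.7150016505241905	2.0687191357243844	2.0370945792522708	2.2626729236054555
case_0005	2.7413979566951894	2.324809222075805	2.3886634208056674	2.2105296617044692
case_0006	2.4960153551913407	2.2329364673266929	2.2540903428132286	2.1969273127199824
case_0007	2.7346496387971051	2.3448827292287393	2.3525630023758897	2.2188220980320681
case_0008	3.0216329598239047	2.1297638672031773	2.2194586919386792	2.2002306599658263
control_0001	2.7114585771889366	2.3413856842977059	2.1575675810889674	2.2204849015522625
control_0002	2.6761888288273408	2.0388044570671497	2.0708992354323281	2.1740075782336716
control_0003	2.6782058343515809	2.178090571201369	2.2443544411080465	2.2242083691218539
control_0004	2.881302176370367	2.6094637078323188	2.3026496151811524	2.2465790120055757
control_0005	2.6188700680360428	2.2502302145815047	2.2040364121398448	2.2013701132806913
control_0006	2.7821187179300955	2.3455872043691524	2.2523412721759843	2.2572077157804178
control_0007	2.7365718765943639	2.1982057754702113	1.9816995276443641	2.2262373359686225
control_0008	2.6237326129203913	2.2221798444094585	2.5274559912308456	2.2048498233654028
control_0009	2.725582245518217	2.2283556840273917	2.2745820675079651	2.3038598448569911
control_0010	2.3311067943235688	1.9097274446214456	1.8927454503257115	2.2123667923269883
control_0011	2.3257857610767805	1.9889248805108923	2.2665858773387959	2.1970237967997535
control_0012	2.9505447193689607	2.6019823087947618	2.3588445549371158	2.1897839445910678
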