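table,stratification,finding,group_a,group_b,pos_a,n_a,pos_b,n_b,printed_chi2,printed_p,known_discrepancy
t4,severity,extension_lt6_spaces,mild,moderate_severe,61,76,3,30,44.3,0.00,FALSE
t4,severity,extension_6_12_spaces,mild,moderate_severe,15,76,18,30,16.2,0.00,FALSE
t4,severity,extension_gt12_spaces,mild,moderate_severe,0,76,9,30,24.9,0.00,FALSE
t4,oxygen,extension_lt6_spaces,no_oxygen,oxygen,61,77,3,29,41.7,0.00,FALSE
t4,oxygen,extension_6_12_spaces,no_oxygen,oxygen,16,77,17,29,14,0.00,FALSE
t4,oxygen,extension_gt12_spaces,no_oxygen,oxygen,0,77,9,29,26.1,0.00,FALSE
t5,severity,consolidation_none,mild,moderate_severe,53,76,5,30,24.4,0.00,FALSE
t5,severity,consolidation_subcm,mild,moderate_severe,20,76,12,30,1.9,0.16,FALSE
t5,severity,consolidation_ge1cm,mild,moderate_severe,3,76,13,30,26.4,0.00,TRUE
t5,oxygen,consolidation_none,no_oxygen,oxygen,53,77,5,29,22.6,0.00,FALSE
t5,oxygen,consolidation_subcm,no_oxygen,oxygen,20,77,12,29,2.3,0.1,FALSE
t5,oxygen,consolidation_ge1cm,no_oxygen,oxygen,4,77,12,29,21.5,0.00,FALSE
t6,srv,anterolateral_normal,srv_negative,srv_positive,27,33,37,73,9.21,0.00,FALSE
t6,srv,anterolateral_diffuse_spared,srv_negative,srv_positive,5,33,30,73,6.92,0.00,FALSE
t6,srv,anterolateral_diffuse_consolidation,srv_negative,srv_positive,1,33,6,73,0.9,0.31,FALSE
t6,srv,extension_lt6_spaces,srv_negative,srv_positive,22,33,42,73,0.7,0.3,FALSE
t6,srv,extension_6_12_spaces,srv_negative,srv_positive,9,33,24,73,0.3,0.5,FALSE
t6,srv,extension_gt12_spaces,srv_negative,srv_positive,2,33,7,73,0.3,0.5,FALSE
t6,srv,consolidation_none,srv_negative,srv_positive,22,33,36,73,2.7,0.09,FALSE
t6,srv,consolidation_subcm,srv_negative,srv_positive,7,33,25,73,1.8,0.17,FALSE
t6,srv,consolidation_ge1cm,srv_negative,srv_positive,4,33,12,73,0.3,0.5,FALSE
t6,srv,interstitial_none,srv_negative,srv_positive,8,33,14,73,0.3,0.5,FALSE
t6,srv,interstitial_focal,srv_negative,srv_positive,20,33,37,73,0.9,0.3,FALSE
t6,srv,interstitial_confluent,srv_negative,srv_positive,5,33,22,73,2.6,0.1,FALSE
t6,srv,area_posterior_only,srv_negative,srv_positive,23,33,33,73,5.4,0.01,FALSE
t6,srv,area_anterior_only,srv_negative,srv_positive,3,33,3,73,1.06,0.3,FALSE
t6,srv,area_both,srv_negative,srv_positive,3,33,32,72,12.7,0.00,FALSE
t6,srv,area_none,srv_negative,srv_positive,4,33,5,72,0.8,0.3,FALSE
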