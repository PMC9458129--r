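label,reactants,products,rate_constant
trail_binding,TRAIL + DR,DISC,0.002
c8_activation,DISC + C8_pro,DISC + C8,0.00396267
bid_cleavage_c8,C8 + Bid,C8 + tBid,1.27398e-05
calpain_activation,Ca + Ca + Calpain_pro,Ca + Ca + Calpain,6
calpain_inhibition,Calpain + Calpastatin,Calp_CStat,20
tbid_priming_calpain,Calpain + tBid,Calpain + tBid_m,0.17
xiap_degradation_calpain,Calpain + XIAP,Calpain,0.042
bax_activation,tBid + Bax,tBid + Bax_a,1.19648e-05
bax_activation_primed,tBid_m + Bax,tBid_m + Bax_a,2.84201e-05
bax_bcl2_binding,Bax_a + Bcl2,Bax_Bcl2,0.001
bax_dimerization,Bax_a + Bax_a,Bax_d,3.00664e-06
pore_formation,Bax_d + Bax_d,Pore,3.46165e-06
smac_release,Pore + Smac_mito,Pore + Smac_cyto,0.000226736
cytc_release,Pore + CytC_mito,Pore + CytC_cyto,0.01
smac_xiap_binding,Smac_cyto + XIAP,Smac_XIAP,0.000214697
smac_clearance,Smac_cyto,Smac_deg,0.0438154
apoptosome_formation,CytC_cyto + Apaf,Apop,5e-05
c3_activation,Apop + C3_pro,Apop + C3,3e-05
c3_xiap_binding,C3 + XIAP,C3_XIAP,2.33455e-05
smac_displacement,Smac_cyto + C3_XIAP,Smac_XIAP + C3,1.02454e-06
parp_cleavage,C3 + PARP,C3 + cPARP,1.29757e-05
xiap_turnover,XIAP,,0.0327568
c3_xiap_turnover,C3_XIAP,C3,0.0327568
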