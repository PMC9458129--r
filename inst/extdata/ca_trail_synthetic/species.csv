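name,compartment,initial_amount
TRAIL,extracellular,3000
DR,membrane,1000
DISC,membrane,0
C8_pro,cytosol,10000
C8,cytosol,0
Ca,cytosol_uM,0
Calpain_pro,cytosol,200
Calpain,cytosol,0
Calpastatin,cytosol,194
Calp_CStat,cytosol,0
Bid,cytosol,60000
tBid,cytosol,0
tBid_m,mito_membrane,0
Bax,cytosol,2098830
Bax_a,mito_membrane,0
Bcl2,cytosol,1980000
Bax_Bcl2,cytosol,0
Bax_d,mito_membrane,0
Pore,mito_membrane,0
Smac_mito,mitochondria,98198.4
Smac_cyto,cytosol,0
XIAP,cytosol,101000
Smac_XIAP,cytosol,0
Smac_deg,cytosol,0
CytC_mito,mitochondria,1e+05
CytC_cyto,cytosol,0
Apaf,cytosol,1e+05
Apop,cytosol,0
C3_pro,cytosol,10000
C3,cytosol,0
C3_XIAP,cytosol,0
PARP,nucleus,1e+06
cPARP,nucleus,0
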