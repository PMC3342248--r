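species,plot_area_m2,stems_per_m2,biomass_kg_per_m2
ARPA,4,5.333,14.747
CECO,4,1.667,1.189
CEIN,4,7.875,10.427
CEPA,4,3.250,1.527
CHSE,4,3.167,1.464
COCO,4,1.000,1.565
COSE,4,8.667,6.087
LEDA,4,0.250,2.430
VAUL,4,0.083,1.069
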