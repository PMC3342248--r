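species,component,form,c0,c1,dbh_min_cm,dbh_max_cm,rmse_log,source_id
ABCO,bole,log10_linear,-1.30,2.45,1,100,0.10,demo_fir_bole
ABCO,bark,log10_linear,-2.20,2.30,1,250,0.14,demo_fir_bark
ABCO,branch,log10_linear,-2.00,2.20,1,110,0.16,demo_fir_branch
ABCO,foliage,log10_linear,-2.10,2.00,1,110,0.18,demo_fir_foliage
ABPR,bole,log10_linear,-1.25,2.45,50,250,0.12,demo_noble_bole
PILA,bole,log10_linear,-1.35,2.45,1,179.6,0.12,demo_sugar_bole
PILA,bark,log10_linear,-2.10,2.30,1,250,0.15,demo_sugar_bark
PSME,bole,log10_linear,-1.30,2.45,1,250,0.11,demo_df_bole
PSME,branch,log10_linear,-2.30,2.35,1,162,0.17,demo_df_branch
PSME,foliage,log10_linear,-2.40,2.10,1,162,0.19,demo_df_foliage
CADE,whole,log10_linear,-1.50,2.45,1,250,0.14,demo_cedar_whole
CONU,whole,log10_linear,-1.70,2.35,1,100,0.15,demo_dogwood_whole
QUKE,whole,log10_linear,-1.55,2.40,1,100,0.12,demo_oak_whole
PRSP,whole,log10_linear,-1.80,2.30,1,100,0.20,demo_prunus_whole
ABMA,whole,log10_linear,-1.35,2.50,1,250,0.10,demo_redfir_whole
SASC,whole,log10_linear,-1.80,2.30,1,100,0.20,demo_willow_whole
PIPO,whole,log10_linear,-1.40,2.45,1,250,0.11,demo_ponderosa_whole
RHCA,whole,log10_linear,-1.90,2.30,1,100,0.20,demo_coffeeberry_whole
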