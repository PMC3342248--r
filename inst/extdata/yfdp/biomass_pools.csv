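pool,total_Mg_ha,large_Mg_ha
live_trees,503.804,248.896
snags,42.958,25.562
woody_debris,53.099,19.444
shrubs,4.103,NA
fine_fuels,48.034,NA
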