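species,proxy_species,density_scale,biomass_scale
SARA,COCO,1,1
RHOC,VAUL,1,1
RINE,VAUL,1,1
RIRO,VAUL,0,0.5
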