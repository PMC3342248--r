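species,family,cover_m2
ARPA,Ericaceae,2524
CECO,Rhamnaceae,1220
CEIN,Rhamnaceae,194
CEPA,Rhamnaceae,187
CHSE,Fagaceae,13082
COCO,Betulaceae,13310
COSE,Cornaceae,2320
LEDA,Ericaceae,2151
VAUL,Ericaceae,2937
SARA,Adoxaceae,13
RHOC,Ericaceae,687
RINE,Grossulariaceae,7
RIRO,Grossulariaceae,66
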