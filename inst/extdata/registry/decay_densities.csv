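species_group,decay_class,density_kg_m3
pine,1,400
pine,2,380
pine,3,350
pine,4,300
pine,5,220
fir,1,370
fir,2,350
fir,3,320
fir,4,280
fir,5,200
cedar,1,380
cedar,2,360
cedar,3,330
cedar,4,290
cedar,5,210
hardwood,1,550
hardwood,2,500
hardwood,3,430
hardwood,4,350
hardwood,5,250
unknown,1,400
unknown,2,370
unknown,3,330
unknown,4,280
unknown,5,210
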