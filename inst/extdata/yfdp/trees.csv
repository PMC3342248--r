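species,family,n_ge1,n_ge10,n_ge100
ABCO,Pinaceae,24481,9634,103
PILA,Pinaceae,4748,2166,339
CONU,Cornaceae,2368,287,0
CADE,Cupressaceae,1592,685,45
QUKE,Fagaceae,1109,735,0
PRSP,Rosaceae,128,0,0
ABMA,Pinaceae,11,5,1
SASC,Salicaceae,11,0,0
PSME,Pinaceae,6,3,1
PIPO,Pinaceae,2,1,0
RHCA,Rhamnaceae,1,0,0
TOTAL,,34458,13516,489
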