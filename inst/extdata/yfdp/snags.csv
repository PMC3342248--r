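species,n_ge10,n_ge100
ABCO,1971,64
PILA,530,133
QUKE,127,0
CADE,46,5
PSME,1,1
CONU,1,0
UNKN,21,7
TOTAL,2697,210
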