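Wfs1
Pou3f1
Gpr161
Slc17a7
Prox1
Grin1
Gria1
Camk2a
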