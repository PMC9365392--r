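Wfs1
Fibcd1
Pou3f1
Gpr161
Plekha2
Slc17a7
Prox1
Dcn
Actb
Gapdh
Calb1
Calb2
Grin1
Gria1
Camk2a
Syp
Mef2c
Nrgn
Ncdn
Cplx2
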