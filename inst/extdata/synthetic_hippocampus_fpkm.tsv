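region	dDG	dDG	dDG	dCA3	dCA3	dCA3	dCA2	dCA2	dCA2	dCA1	dCA1	dCA1
replicate	1	2	3	1	2	3	1	2	3	1	2	3
Wfs1	5	6	7	5	6	7	5	6	7	30	31	32
Fibcd1	3	4	5	3	4	5	3	4	5	18	20	22
Pou3f1	7	8	9	7	8	9	7	8	9	11	12	13
Gpr161	10	11	12	10	11	12	10	11	12	24	26	28
Plekha2	1	1.2	1.4	1	1.2	1.4	1	1.2	1.4	4	4.5	5
Slc17a7	30	32	34	30	32	34	30	32	34	40	42	44
Prox1	50	52	54	4	5	6	4	5	6	4	5	6
Dcn	8	9	10	8	9	10	8	9	10	8	9	10
Actb	100	102	104	100	102	104	100	102	104	100	102	104
Gapdh	55	56	57	55	56	57	55	56	57	55	56	57
Calb1	12	13	14	12	14	13	13	12	14	12	13	14
Calb2	2	2.2	2.4	2	2.2	2.4	2	2.2	2.4	2	2.2	2.4
Grin1	22	23	24	22	23	24	22	23	24	22	23	24
Gria1	15	16	17	15	16	17	15	16	17	15	16	17
Camk2a	60	62	64	60	62	64	60	62	64	60	62	64
Syp	33	34	35	33	34	35	33	34	35	33	34	35
Mef2c	9	10	11	9	10	11	9	10	11	9	10	11
Nrgn	45	46	47	45	46	47	45	46	47	45	46	47
Ncdn	18	19	20	18	19	20	18	19	20	18	19	20
Cplx2	6	7	8	6	7	8	6	7	8	6	7	8
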