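cancer_type	group	n_male	n_female
THCA	adult	157	415
ACC	adult	31	48
PCPG	adult	84	103
SARC	adult	120	145
DLBC	adult	22	26
LUAD	adult	265	311
CHOL	adult	22	23
THYM	adult	63	59
COAD	adult	257	235
READ	adult	90	80
LAML	adult	93	80
LGG	adult	291	238
PAAD	adult	101	82
UVM	adult	45	35
KICH	adult	52	39
SKCM	adult	293	180
GBM	adult	107	59
STAD	adult	291	159
KIRC	adult	398	208
LIHC	adult	280	143
BLCA	adult	311	116
KIRP	adult	236	87
HNSC	adult	415	151
LUSC	adult	408	144
MESO	adult	71	16
ESCA	adult	165	31
NBL	pediatric	104	105
EPN	pediatric	44	32
HGG	pediatric	43	56
MB	pediatric	68	37
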