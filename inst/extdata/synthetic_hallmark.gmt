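SYNTH_EFFECTOR_CYTOTOXICITY	synthetic effector/trafficking gene set over the generator's analogs	Gzmb	Gzma	Prf1	Ccr5	Cxcr6	Ifng
SYNTH_ANTIGEN_PRESENTATION	synthetic MHC class I/II analog set	H2-K1	H2-D1	B2m	H2-Aa	H2-Ab1	H2-Eb1	Cd74
SYNTH_EPITHELIAL_JUNCTION	synthetic epithelial program analog set	Cdh1	Epcam	Cldn4	Cldn7	Ocln	Dsp	Krt8	Krt18
SYNTH_MESENCHYMAL_MATRIX	synthetic mesenchymal program analog set	Vim	Snai1	Twist1	Zeb1	Fn1	Mmp11	Mmp2	S100a4
SYNTH_RANDOM_A	synthetic null set of filler genes	Gene0001	Gene0002	Gene0003	Gene0004	Gene0005	Gene0006	Gene0007	Gene0008
SYNTH_RANDOM_B	synthetic null set of filler genes	Gene0010	Gene0020	Gene0030	Gene0040	Gene0050	Gene0060	Gene0070	Gene0080	Gene0090	Gene0100
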