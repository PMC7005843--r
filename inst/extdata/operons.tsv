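operon_id	member_families	min_fraction	category_on_success	category_on_partial
mtrCAB	mtrC,mtrA,mtrB	1.0	iron_reduction	probable_iron_reduction
mam	mamA,mamB,mamE,mamK,mamL,mamM,mamO,mamP,mamQ,mamI	0.5	magnetosome_formation	-
foxABC	foxA,foxB,foxC	0.6	iron_oxidation	-
foxEYZ	foxE,foxY,foxZ	0.6	iron_oxidation	-
pioABC	pioA,pioB,pioC	0.6	iron_oxidation	-
flavin	fmnA,dmkA,fmnB,pplA,ndh2,eetA,eetB,dmkB	0.5	iron_reduction	-
dfe0448_0451	DFE_0448,DFE_0449,DFE_0450,DFE_0451	0.75	iron_reduction	-
dfe0461_0465	DFE_0461,DFE_0462,DFE_0463,DFE_0464,DFE_0465	0.6	iron_reduction	-
slayer	slayerA,slayerB,slayerC	0.6	iron_reduction	-
pcc	omaB,ombB,omcB	0.6	iron_reduction	-
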