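rule_id	category	required_families	any_of_families	min_any	forbidden_families	operon_id	scope
cyc2_cluster1	iron_oxidation	cyc2_cluster1	-	0	-	-	neighborhood
cyc2_cluster2	iron_oxidation	cyc2_cluster2	-	0	-	-	neighborhood
sulfocyanin	iron_oxidation	sulfocyanin	-	0	-	-	neighborhood
cyc1	iron_oxidation	cyc1	-	0	-	-	neighborhood
foxABC	iron_oxidation	-	foxA,foxB,foxC	2	-	foxABC	neighborhood
foxEYZ	iron_oxidation	foxE	foxY,foxZ	1	-	foxEYZ	neighborhood
pioAB	iron_oxidation	pioA,pioB	-	0	-	pioABC	neighborhood
cyc2_cluster3	possible_iron_oxidation_and_possible_iron_reduction	cyc2_cluster3	-	0	-	-	neighborhood
mtoA	possible_iron_oxidation_and_possible_iron_reduction	mtoA	-	0	mtrC	-	neighborhood
mtrCAB	iron_reduction	mtrC,mtrA,mtrB	-	0	-	mtrCAB	neighborhood
cymA	iron_reduction	cymA	-	0	-	-	neighborhood
omcF	iron_reduction	omcF	-	0	-	-	neighborhood
omcS	iron_reduction	omcS	-	0	-	-	neighborhood
omcZ	iron_reduction	omcZ	-	0	-	-	neighborhood
flavin	iron_reduction	-	fmnA,dmkA,fmnB,pplA,ndh2,eetA,eetB,dmkB	4	-	flavin	neighborhood
dfe0448_0451	iron_reduction	-	DFE_0448,DFE_0449,DFE_0450,DFE_0451	3	-	dfe0448_0451	neighborhood
dfe0461_0465	iron_reduction	-	DFE_0461,DFE_0462,DFE_0463,DFE_0464,DFE_0465	3	-	dfe0461_0465	neighborhood
slayer	iron_reduction	-	slayerA,slayerB,slayerC	2	-	slayer	neighborhood
pcc	iron_reduction	-	omaB,ombB,omcB	2	-	pcc	neighborhood
mtrAB	probable_iron_reduction	mtrA,mtrB	-	0	mtrC	mtrCAB	neighborhood
mtrCB	probable_iron_reduction	mtrC,mtrB	-	0	mtrA	mtrCAB	neighborhood
mtoAB_mtrC	probable_iron_reduction	mtoA,mtoB,mtrC	-	0	-	-	neighborhood
mam	magnetosome_formation	-	mamA,mamB,mamE,mamK,mamL,mamM,mamO,mamP,mamQ,mamI	5	-	mam	neighborhood
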