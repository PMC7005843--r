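family_id	category	method	model_ref	cutoff	min_length	min_heme_motifs	operon_group	source
efeU	iron_transport	hmm	efeU	30	-	-	-	custom
efeO	iron_transport	hmm	efeO	30	-	-	-	custom
efeB	iron_transport	hmm	efeB	30	-	-	-	custom
fbpA	iron_transport	hmm	fbpA	30	-	-	-	custom
fbpB	iron_transport	hmm	fbpB	30	-	-	-	custom
fbpC	iron_transport	hmm	fbpC	30	-	-	-	custom
sfuA	iron_transport	hmm	sfuA	30	-	-	-	custom
feoA	iron_transport	hmm	feoA	30	-	-	-	Pfam
feoB	iron_transport	hmm	feoB	30	-	-	-	Pfam
futA1	iron_transport	hmm	futA1	30	-	-	-	custom
futA2	iron_transport	hmm	futA2	30	-	-	-	custom
futB	iron_transport	hmm	futB	30	-	-	-	custom
futC	iron_transport	hmm	futC	30	-	-	-	custom
yfeA	iron_transport	hmm	yfeA	30	-	-	-	custom
hemO	heme_oxygenase	hmm	hemO	30	-	-	-	custom
hmuO	heme_oxygenase	hmm	hmuO	30	-	-	-	custom
pigA	heme_oxygenase	hmm	pigA	30	-	-	-	custom
isdG	heme_oxygenase	hmm	isdG	30	-	-	-	custom
isdI	heme_oxygenase	hmm	isdI	30	-	-	-	custom
mhuD	heme_oxygenase	hmm	mhuD	30	-	-	-	custom
chuS	heme_oxygenase	hmm	chuS	30	-	-	-	custom
hugZ	heme_oxygenase	hmm	hugZ	30	-	-	-	custom
hasA	heme_transport	hmm	hasA	30	-	-	-	custom
hasR	heme_transport	hmm	hasR	30	-	-	-	custom
isdX1	heme_transport	hmm	isdX1	30	-	-	-	custom
isdX2	heme_transport	hmm	isdX2	30	-	-	-	custom
hxuA	heme_transport	hmm	hxuA	30	-	-	-	custom
rv0203	heme_transport	hmm	rv0203	30	-	-	-	custom
hmuY	heme_transport	hmm	hmuY	30	-	-	-	custom
hutZ	heme_transport	hmm	hutZ	30	-	-	-	custom
phuS	heme_transport	hmm	phuS	30	-	-	-	custom
tbpA	heme_transport	hmm	tbpA	30	-	-	-	custom
tbpB	heme_transport	hmm	tbpB	30	-	-	-	custom
iucA	siderophore_synthesis	hmm	iucA	30	-	-	-	custom
iucC	siderophore_synthesis	hmm	iucC	30	-	-	-	custom
entF	siderophore_synthesis	hmm	entF	30	-	-	-	Pfam
pchE	siderophore_synthesis	hmm	pchE	30	-	-	-	custom
asbA	siderophore_synthesis	hmm	asbA	30	-	-	-	custom
asbB	siderophore_synthesis	hmm	asbB	30	-	-	-	custom
dhbF	siderophore_synthesis	hmm	dhbF	30	-	-	-	Pfam
mbtB	siderophore_synthesis	hmm	mbtB	30	-	-	-	custom
pvdL	siderophore_synthesis	hmm	pvdL	30	-	-	-	custom
vibF	siderophore_synthesis	hmm	vibF	30	-	-	-	custom
tonB	siderophore_transport	hmm	tonB	30	-	-	-	Pfam
exbB	siderophore_transport	hmm	exbB	30	-	-	-	Pfam
exbD	siderophore_transport	hmm	exbD	30	-	-	-	Pfam
fhuA	siderophore_transport	hmm	fhuA	30	-	-	-	custom
fepA	siderophore_transport	hmm	fepA	30	-	-	-	custom
fecA	siderophore_transport	hmm	fecA	30	-	-	-	custom
fptA	siderophore_transport	hmm	fptA	30	-	-	-	custom
fpvA	siderophore_transport	hmm	fpvA	30	-	-	-	custom
piuA	siderophore_transport	hmm	piuA	30	-	-	-	custom
pirA	siderophore_transport	hmm	pirA	30	-	-	-	custom
viuA	siderophore_transport	hmm	viuA	30	-	-	-	custom
yqjH	siderophore_transport	hmm	yqjH	30	-	-	-	custom
fur	iron_gene_regulation	hmm	fur	30	-	-	-	Pfam
feoC	iron_gene_regulation	hmm	feoC	30	-	-	-	custom
dtxR	iron_gene_regulation	hmm	dtxR	30	-	-	-	Pfam
ideR	iron_gene_regulation	hmm	ideR	30	-	-	-	custom
pchR	iron_gene_regulation	hmm	pchR	30	-	-	-	custom
fecR	iron_gene_regulation	hmm	fecR	30	-	-	-	custom
yqjI	iron_gene_regulation	hmm	yqjI	30	-	-	-	custom
cyc1	iron_oxidation	hmm	cyc1	30	-	-	-	custom
cyc2_cluster1	iron_oxidation	hmm	cyc2_cluster1	30	375	1	-	custom
cyc2_cluster2	iron_oxidation	hmm	cyc2_cluster2	30	375	1	-	custom
sulfocyanin	iron_oxidation	hmm	sulfocyanin	30	-	-	-	custom
foxA	iron_oxidation	hmm	foxA	30	-	-	foxABC	custom
foxB	iron_oxidation	hmm	foxB	30	-	-	foxABC	custom
foxC	iron_oxidation	hmm	foxC	30	-	-	foxABC	custom
foxE	iron_oxidation	hmm	foxE	30	-	-	foxEYZ	custom
foxY	iron_oxidation	hmm	foxY	30	-	-	foxEYZ	custom
foxZ	iron_oxidation	hmm	foxZ	30	-	-	foxEYZ	custom
pioA	iron_oxidation	hmm	pioA	30	-	-	pioABC	custom
pioB	iron_oxidation	hmm	pioB	30	-	-	pioABC	custom
pioC	iron_oxidation	hmm	pioC	30	-	-	pioABC	custom
mtoA	possible_iron_oxidation_and_possible_iron_reduction	hmm	mtoA	30	-	-	-	custom
mtoB	possible_iron_oxidation_and_possible_iron_reduction	hmm	mtoB	30	-	-	-	custom
cyc2_cluster3	possible_iron_oxidation_and_possible_iron_reduction	hmm	cyc2_cluster3	30	375	1	-	custom
cymA	iron_reduction	hmm	cymA	30	-	-	-	custom
mtrA	iron_reduction	hmm	mtrA	30	-	-	mtrCAB	custom
mtrB	iron_reduction	hmm	mtrB	30	-	-	mtrCAB	TIGRFAMS
mtrC	iron_reduction	hmm	mtrC	30	-	-	mtrCAB	TIGRFAMS
omcF	iron_reduction	hmm	omcF	30	-	-	-	custom
omcS	iron_reduction	hmm	omcS	30	-	-	-	custom
omcZ	iron_reduction	hmm	omcZ	30	-	-	-	custom
fmnA	iron_reduction	hmm	fmnA	30	-	-	flavin	custom
dmkA	iron_reduction	hmm	dmkA	30	-	-	flavin	custom
fmnB	iron_reduction	hmm	fmnB	30	-	-	flavin	custom
pplA	iron_reduction	hmm	pplA	30	-	-	flavin	custom
ndh2	iron_reduction	hmm	ndh2	30	-	-	flavin	custom
eetA	iron_reduction	hmm	eetA	30	-	-	flavin	custom
eetB	iron_reduction	hmm	eetB	30	-	-	flavin	custom
dmkB	iron_reduction	hmm	dmkB	30	-	-	flavin	custom
DFE_0448	iron_reduction	hmm	DFE_0448	30	-	-	dfe0448_0451	custom
DFE_0449	iron_reduction	hmm	DFE_0449	30	-	-	dfe0448_0451	custom
DFE_0450	iron_reduction	hmm	DFE_0450	30	-	-	dfe0448_0451	custom
DFE_0451	iron_reduction	hmm	DFE_0451	30	-	-	dfe0448_0451	custom
DFE_0461	iron_reduction	hmm	DFE_0461	30	-	-	dfe0461_0465	custom
DFE_0462	iron_reduction	hmm	DFE_0462	30	-	-	dfe0461_0465	custom
DFE_0463	iron_reduction	hmm	DFE_0463	30	-	-	dfe0461_0465	custom
DFE_0464	iron_reduction	hmm	DFE_0464	30	-	-	dfe0461_0465	custom
DFE_0465	iron_reduction	hmm	DFE_0465	30	-	-	dfe0461_0465	custom
slayerA	iron_reduction	homology	slayerA	1e-10	-	-	slayer	custom
slayerB	iron_reduction	homology	slayerB	1e-10	-	-	slayer	custom
slayerC	iron_reduction	homology	slayerC	1e-10	-	-	slayer	custom
omaB	iron_reduction	homology	omaB	1e-10	-	-	pcc	custom
ombB	iron_reduction	homology	ombB	1e-10	-	-	pcc	custom
omcB	iron_reduction	homology	omcB	1e-10	-	-	pcc	custom
bfr	iron_storage	hmm	bfr	30	-	-	-	Pfam
dpsA	iron_storage	hmm	dpsA	30	-	-	-	Pfam
ftn	iron_storage	hmm	ftn	30	-	-	-	Pfam
mamA	magnetosome_formation	hmm	mamA	30	-	-	mam	custom
mamB	magnetosome_formation	hmm	mamB	30	-	-	mam	custom
mamE	magnetosome_formation	hmm	mamE	30	-	-	mam	custom
mamK	magnetosome_formation	hmm	mamK	30	-	-	mam	custom
mamL	magnetosome_formation	hmm	mamL	30	-	-	mam	custom
mamM	magnetosome_formation	hmm	mamM	30	-	-	mam	custom
mamO	magnetosome_formation	hmm	mamO	30	-	-	mam	custom
mamP	magnetosome_formation	hmm	mamP	30	-	-	mam	custom
mamQ	magnetosome_formation	hmm	mamQ	30	-	-	mam	custom
mamI	magnetosome_formation	hmm	mamI	30	-	-	mam	custom
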