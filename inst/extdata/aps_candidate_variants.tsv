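gene	full_name	rsid	chrom	pos	transcript	protein_change	ref	alt	allele_source
ADCY3	Adenylate cyclase 3	rs754839662	2	25050928	NM_004036.3	p.Val759Met	C	T	printed
ATP2B2	ATPase plasma membrane Ca2+ transporting 2	rs751257556	3	10382352	NM_001001331.2	p.Ala985Val	G	A	printed
BCL3	BCL3 transcription coactivator	rs747655476	19	45262063	NM_005178.4	p.Thr381Asn	C	A	printed
CC2D1A	Coiled-coil and C2 domain containing 1A	.	19	14028928	NM_017721.4	p.Arg265Leu	G	T	cdna_notation
CROCC	Ciliary rootlet coiled-coil, rootletin	rs1444279934	1	17270657	NM_014675.3	p.Gln624Leu	A	T	printed
CRTC3	CREB regulated transcription coactivator 3	.	15	91083301	NM_022769.4	p.Leu55Phe	C	T	cdna_notation
FAT2	FAT atypical cadherin 2	rs761199516	5	150945648	NM_001447.2	p.Ala949Ser	C	A	printed
GRM7	Glutamate metabotropic receptor 7	rs1480175679	3	7494339	NM_181874.2	p.Lys407Thr	A	C	printed
HSPG2	Heparan sulfate proteoglycan 2	rs766963773	1	22207015	NM_005529.5	p.Arg679His	C	T	printed
IFNA17	Interferon alpha 17	.	9	21227835	NM_021268.2	p.Tyr113Phe	A	T	cdna_notation
IMPA2	Inositol monophosphatase 2	rs1423846345	18	12009980	NM_014214.2	p.Val110Ala	T	C	printed
KIF14	Kinesin family member 14	rs373895990	1	200573037	NM_014875.2	p.Arg598Gln	C	T	printed
LTBP2	Latent transforming growth factor beta binding protein 2	rs1310944162	14	74995323	NM_000428.2	p.Ala744Val	G	A	printed
MAP3K10	Mitogen-activated protein kinase kinase kinase 10	.	19	40698296	NM_002446.3	p.Glu120Lys	G	A	cdna_notation
MCM8	Minichromosome maintenance 8 homologous recombination repair factor	rs768426546	20	5953350	NM_001281521.1	p.Arg451His	G	A	printed
MRPL48	Mitochondrial ribosomal protein L48	rs745995390	11	73555903	NM_016055.5	p.Asp85Tyr	G	T	printed
MUC16	Mucin 16	rs200972932	19	9067504	NM_024690.2	p.Glu6648Lys	C	T	printed
OR2F1	Olfactory receptor family 2 subfamily F member 1	rs777034277	7	143657370	NM_012369.2	p.Phe103Leu	T	C	printed
OXNAD1	Oxidoreductase NAD binding domain containing 1	rs1456594626	3	16343175	NM_138381.3	p.Phe159Glu	T	G	printed
OXNAD1	Oxidoreductase NAD binding domain containing 1	rs1159857217	3	16343176	NM_138381.3	p.Phe159Glu	T	A	printed
OXNAD1	Oxidoreductase NAD binding domain containing 1	rs1390159575	3	16343177	NM_138381.3	p.Phe159Glu	C	G	printed
PDZD2	PDZ domain containing 2	rs1345334581	5	32098731	NM_178140.2	p.Pro2737Ala	C	G	printed
PLA2G6	Phospholipase A2 group VI	rs780423461	22	38528920	NM_003560.2	p.Cys332Ser	C	G	printed
SRGAP3	SLIT-ROBO Rho GTPase activating protein 3	rs764134718	3	9146464	NM_014850.3	p.Arg108Gln	C	T	printed
USP32	Ubiquitin specific peptidase 32	.	17	58313569	NM_032582.3	p.Leu390Pro	T	C	cdna_notation
ZFAT	Zinc finger and AT-hook domain containing	rs748138009	8	135596174	NM_020863.3	p.Arg930Cys	G	A	printed
ZNF462	Zinc finger protein 462	.	9	109686419	NM_021224.4	p.Asn76Tyr	A	T	cdna_notation
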