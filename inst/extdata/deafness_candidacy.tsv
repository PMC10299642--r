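gene	gene_coordinates	locus	locus_coordinates	markers	causative_gene
ANKEF1	20:10034987-10058303	n/a	n/a	n/a	n/a
ODF3L2	19:463346-474880	DFNB72	19:4949401-6113471	D19S216-D19S1034	GIPC3
ODF3L2	19:463346-474880	DFNA57	19:7806762-18232460	D19S912-D19S212	unknown
SAXO2	15:82262818-82284927	DFNA30	15:87053920-94168232	D15S151-D15S130	unknown
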