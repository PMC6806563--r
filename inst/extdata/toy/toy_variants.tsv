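Type	Name	ClinicalSignificance	Assembly	Chromosome	Start	ReferenceAllele	AlternateAllele	VariationID	GeneSymbol	PhenotypeIDS
single nucleotide variant	SYN(SYN_CR0001):c.223G>A	Pathogenic	GRCh38	contig1	223	G	A	SYN_CR0001		
single nucleotide variant	SYN(SYN_CR0002):c.448C>T	Pathogenic	GRCh38	contig1	448	C	T	SYN_CR0002		
single nucleotide variant	SYN(SYN_CR0003):c.514G>A	Pathogenic	GRCh38	contig1	514	G	A	SYN_CR0003		
single nucleotide variant	SYN(SYN_CO0001):c.298A>G	Pathogenic	GRCh38	contig1	298	A	G	SYN_CO0001		
single nucleotide variant	SYN(SYN_CO0002):c.307A>G	Pathogenic	GRCh38	contig1	307	A	G	SYN_CO0002		
single nucleotide variant	SYN(SYN_CO0003):c.54T>C	Pathogenic	GRCh38	contig1	54	T	C	SYN_CO0003		
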