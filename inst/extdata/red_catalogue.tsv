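gene	disease	motif	cutoff_units	cutoff_bp	region_class	chrom	start	end	interruption_motifs	zygosity	motif_change
AR	Spinal and bulbar muscular atrophy	CAG	36	108	Coding	chrX	1000000	1000063		monoallelic	FALSE
ATN1	Dentatorubral-pallidoluysian atrophy	CAG	35	105	Coding	chr12	2000000	2000045		monoallelic	FALSE
ATXN10	Spinocerebellar ataxia 10	ATTCT	33	165	Intron	chr22	3000000	3000070		monoallelic	FALSE
ATXN1	Spinocerebellar ataxia 1	CAG	39	117	Coding	chr6	4000000	4000087	CAT	monoallelic	FALSE
ATXN2	Spinocerebellar ataxia 2	CAG	32	96	Coding	chr12	5000000	5000066		monoallelic	FALSE
ATXN3	Spinocerebellar ataxia 3	CAG	45	135	Coding	chr14	6000000	6000069		monoallelic	FALSE
PHOX2B	Congenital central hypoventilation syndrome	GCN	NA	NA	Coding	chr4	7000000	7000060		monoallelic	FALSE
ATXN7	Spinocerebellar ataxia 8	CAG	33	99	Coding	chr3	8000000	8000030		monoallelic	FALSE
ATXN8OS	Spinocerebellar ataxia 8	CAG	40	120	3'UTR	chr13	9000000	9000060		monoallelic	FALSE
C9orf72	Frontotemporal dementia and/or amyotrophic lateral sclerosis	GGGGCC	30	180	Intron	chr9	10000000	10000030		monoallelic	FALSE
CACNA1A	Spinocerebellar ataxia 6	CAG	19	57	Coding	chr19	11000000	11000036		monoallelic	FALSE
CNBP	Myotonic dystrophy 2	CCTG	27	108	Intron	chr3	12000000	12000056		monoallelic	FALSE
DMPK	Myotonic dystrophy 1	CTG	36	108	3'UTR	chr19	13000000	13000036		monoallelic	FALSE
FMR1	FMR1-related disorders	CGG	55	165	5'UTR	chrX	14000000	14000090		monoallelic	FALSE
FXN	Friedreich ataxia	GAA	34	102	Intron	chr9	15000000	15000027		monoallelic	FALSE
HTT	Huntington disease	CAG	35	105	Coding	chr4	16000000	16000051		monoallelic	FALSE
JPH3	Huntington disease-like 2	CTG	49	147	Exon	chr16	17000000	17000039		monoallelic	FALSE
NOP56	Spinocerebellar ataxia 36	GGCCTG	15	90	Intron	chr20	18000000	18000042		monoallelic	FALSE
PPP2R2B	Spinocerebellar ataxia 12	CAG	33	99	5'UTR	chr5	19000000	19000039		monoallelic	FALSE
TBP	Spinocerebellar ataxia 17	CAG	43	129	Coding	chr6	20000000	20000105		monoallelic	FALSE
NIPA1	Hereditary Spastic Paraplegia type 6	GCG	NA	NA	5'UTR	chr15	21000000	21000021		monoallelic	FALSE
NOTCH2NL	Neuronal intranuclear inclusion disease	GGC	55	165	5'UTR	chr1	22000000	22000048		monoallelic	FALSE
RFC1	Cerebellar ataxia, neuropathy, and vestibular areflexia syndrome	AAGGG	0	5	Intron	chr4	23000000	23000055		monoallelic	TRUE
PABN1	Oculopharyngeal muscular dystrophy	GCN	NA	NA	Coding	chr14	24000000	24000030		monoallelic	FALSE
CSTB	Progressive myoclonic epilepsy 1A	CCCCGCCCCGCG	4	48	Intron	chr21	25000000	25000036		monoallelic	FALSE
GLS	Global developmental delay, progressive ataxia, and elevated glutamine	GCA	30	90	5'UTR	chr2	26000000	26000042		biallelic	FALSE
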