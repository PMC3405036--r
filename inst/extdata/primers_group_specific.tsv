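name	sequence	orientation	pos_start	pos_end	target_group	citation	deg_printed	tm_printed	flagged	nonstandard	note
ChenBR1	CGCIWTYTACGGIAARGGIGG	forward	18	38	BR	Chen	512	66.6-69.8	0	0	printed degeneracy counts inosine as 4
nifH-f1-forA	GCSTTCTACGGMAAGGGTGG	forward	19	38	Fr	Buergmann	4	63.9-66.7	0	0	
nifH-a1-forA	GCRTTYTACGGYAARGGSGG	forward	19	38	AP	Buergmann	32	60.6-69.1	0	0	
nifHF	TACGGNAARGGSGGNATCGGCAA	forward	25	47	R	Laguerre	64	66.7-73.9	0	0	
primer-3	GGTATYGGYAARTGYACYAC	forward	37	56	RA	Lovell	32	52.6-64.8	0	0	
nifHf1	GGCAAGTCCACCACCCAGC	forward	43	61	Fr	Mirza-a	1	67.0	0	0	
Olsen1	ATYGTCGGYTGYGAYCCSAARGC	forward	106	128	AM	Olson	64	65.0-73.6	0	0	
cyanoF	CGTAGGTTGCGACCCTAAGGCTGA	forward	108	131	Cy	Olson	1	68.8	0	0	
nifH-b1-forB	GGCTGCGATCCCAAGGCTGA	forward	112	131	AB	Buergmann	1	68.3	0	0	
nifH-g1-forB	GGTTGTGACCCGAAAGCTGA	forward	112	131	GP	Buergmann	1	64.1	0	0	
nifH-c1-forB	GGWTGTGATCCWAARGCVGA	forward	112	131	AN	Buergmann	24	58.7-64.3	0	0	
nifH-a2-forB	GGCTGCGATCCGAAGGCCGA	forward	112	131	AP	Buergmann	1	70.3	0	0	
nifH-a1-forB	GGMTGCGAYCCSAARGCSGA	forward	112	131	AP	Buergmann	32	66.2-72.7	0	0	
nifH-f1-forB	GGBTGYGACCCSAASGCYGA	forward	112	131	Fr	Buergmann	48	65.9-72.9	0	0	
nifHFor	ACCCGCCTGATCCTGCACGCCAAGG	forward	136	160	MS	Soares	1	74.7	0	0	
cylnif-F	TAARGCTCAAACTACCGTAT	forward	156	175	Cs	Dyble	2	56.2-57.9	0	0	
NIFH2F	GAAGGTCGGCTACCAGAACA	forward	231	250	TB	Barbieri	1	63.1	0	0	
NIFH5R	AAGTTGATCGAGGTGATGACG	reverse	306	326	TB	Barbieri	1	61.6	0	0	
nifH-269	CCGGCCTCCTCCAGGTA	reverse	325	341	Fr	Mirza-b	1	64.2	0	0	
cylnif-R	ATTTAGACTTCGTTTCCTAC	reverse	356	375	Cs	Dyble	1	54.6	0	0	
NifHRev	ACGATGTAGATTTCCTGGGCCTTGTT	reverse	427	452	MS	Soares	1	67.5	0	0	
primer-4=AQE	GACGATGTAGATYTCCTG	reverse	436	453	RA	Lovell	2	53.8-55.1	0	0	
cyanoR	GCATACATCGCCATCATTTCACC	reverse	460	482	Cy	Olson	1	63.6	0	0	
nifH-f1-rev	GCGTACATSGCCATCATCTC	reverse	463	482	Fr	Buergmann	2	62.2-62.3	0	0	
nifH-b1-rev	GCGTACATGGCCATCATCTC	reverse	463	482	AB	Buergmann	1	62.3	0	0	
nifH-g1-rev	GCGTACATGGCCATCATCTC	reverse	463	482	GP	Buergmann	1	62.3	0	0	
nifH-c1-rev	GCATAYASKSCCATCATYTC	reverse	463	482	AN	Buergmann	8	55.4-62.3	0	0	printed degeneracy 8 inconsistent with sequence (computed 32)
nifH-a2-rev	GCGTAGAGCGCCATCATCTC	reverse	463	482	AP	Buergmann	1	64.0	0	0	
nifH-a1-rev	GCATAGAGCGCCATCATCTC	reverse	463	482	AP	Buergmann	1	62.0	0	0	
Olsen2	ATGGTGTTGGCGGCRTAVAKSGCCATCAT	reverse	466	494	AM	Olson	24	71.5-75.3	0	0	
nifHr	CTCGATGACGGTCATCCGGC	reverse	671	690	Fr	Mirza-a	1	65.9	0	0	
ChenBR2	GGIKCRTAYTSGATIACIGTCAT	reverse	676	698	BR	Chen	1024	63.6-69.1	0	0	printed degeneracy counts inosine as 4
FGPH750	GAAGACGATCCCGACCCCGA	forward	759	778	Fr	Simonet	1	66.8	0	0	
nifHI	AGCATGTCYTCSAGYTCNTCCA	reverse	785	806	R	Laguerre	32	63.3-68.8	0	0	
FGPD913	GGTCGGGACCTCATCCTCGA	reverse	NA	NA	Fr	Simonet	1	66.3	0	0	binding site lies beyond the reference stop codon; window not representable
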