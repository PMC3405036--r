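name	sequence	orientation	pos_start	pos_end	target_group	citation	deg_printed	tm_printed	flagged	nonstandard	note
Nh21F	GCIWTYTAYGGNAARGG	forward	19	35	universal	Deslippe	64	51.8-61.9	0	0	
nifH19F	GCIWTITAYGGNAARGGNGG	forward	19	38	universal	Widmer	128	59.5-69.5	0	0	
Ueda19F	GCIWTYTAYGGIAARGGIGG	forward	19	38	universal	Ueda	16	62.4-67.9	0	0	
IGK3	GCIWTHTAYGGIAARGGIGGIATHGGIAA	forward	19	47	universal	Ando	72	69.4-75.3	0	0	
K07-F	GCGTTCTACGGTAAGGGCGGTATCGGNAAR	forward	19	48	universal	Roesch-b	8	71.0-72.8	0	0	
nifH4	TTYTAYGGNAARGGNGG	forward	22	38	universal	Zani	128	49.8-63.5	0	0	
primer-f	TCTACGGAAAGGGCGGTATCGG	forward	23	44	universal	Flores-Mireles	1	66.5	0	0	
FGPH19	TACGGCAARGGTGGNATHG	forward	25	43	universal	Simonet	24	58.2-66.2	0	0	
IGK-Poly	TACGGYAARGGBGGYATCGG	forward	25	44	universal	Poly	24	60.3-70.6	0	0	renamed to disambiguate from similarly named primers
PicenoF44	TACGG(P/K)AAKGG(P/G)GG(P/K)ATPGG	forward	25	44	universal	Piceno	8	NA	0	1	contains non-IUPAC P/K base codes; excluded from matching and Tm
F1	TAYGGIAARGGIGGIATYGGIAARTC	forward	25	50	universal	Marusina	4096	60.4-74.5	0	0	printed degeneracy counts inosine as 4
MehtaF	GGHAARGGHGGHATHGGNAARTC	forward	28	50	universal	Mehta	1296	57.4-72.9	0	0	
IGK	AARGGNGGNATHGGNAA	forward	31	47	universal	Ohkuma	384	62.1-72.5	0	0	5' linker sequence ATAGGATCC removed
nifHF-Roesch	AAAGGYGGWATCGGYAARTCCACCAC	forward	31	56	universal	Roesch-a	16	66.0-71.6	0	0	renamed to disambiguate from similarly named primers
roeschF-1b	AAAGGYGGWATCCGYAARTCCACCAC	forward	31	56	universal	Ogilvie	16	66.0-71.6	1	0	suspected single-base publication error (C at position 13)
RL28	GGTATYGGYAARTCSACSAC	forward	37	56	universal	Bagwell	32	57.7-64.1	0	0	
KAD3	ATHGTIGGITGYGAYCCIAARGCIGA	forward	106	131	universal	Ando	16	70.1-76.8	0	0	printed degeneracy 16 inconsistent with sequence (computed 24)
469	GGNTGYGAYCCNAARGC	forward	112	128	universal	Poly	128	53.4-67.4	0	0	
nif112	GGITGTGAYCCNAAVGCNGA	forward	112	131	universal	Widmer	96	60.9-70.4	0	0	
nifH-univ-f112	GGITGYGAYCCNAAVGCNGA	forward	112	131	universal	Buergmann	192	60.9-72.7	0	0	
nifH2	TGYGAYCCNAARGCNGA	forward	115	131	universal	Zehr-McReynolds	128	54.0-68.1	0	0	
Kadino	TGYGAYCCIAARGCIGA	forward	115	131	universal	Poly	8	60.2-67.9	0	0	
F2	TGYGAYCCIAAIGCIGA	forward	115	131	universal	Marusina	4	62.3-67.9	0	0	
polF	TGCGAYCCSAARGCBGACTC	forward	115	134	universal	Poly	24	63.8-70.1	0	0	
nifH11	GAYCCNAARGCNGACTC	forward	118	134	universal	Yeager	64	52.7-63.4	0	0	
FGPH273	CTCCGGGCCRCCNGAYTC	reverse	262	279	universal	Simonet	16	63.7-70.7	0	0	name printed with trailing prime mark
nifH-2f	GMRCCIGGIGTIGGYTGYGC	forward	277	296	universal	Fedorov	16	69.2-78.3	0	0	
Cy55Nh428R	CCRCCRCANACMACGTC	reverse	388	404	universal	Deslippe	32	56.6-67.5	0	0	
Ueda407R	AAICCRCCRCAIACIACRTC	reverse	388	407	universal	Ueda	8	63.9-70.6	0	0	
DVV	ATIGCRAAICCICCRCAIACIACRTC	reverse	388	413	universal	Ando	8	71.7-75.8	0	0	
MehtaR	GGCATNGCRAANCCVCCRCANAC	reverse	394	416	universal	Mehta	768	63.2-75.1	0	0	
VCG	ATIGGCATIGCRAAICCICCRCAIAC	reverse	394	419	universal	Ando	4	73.9-76.7	0	0	
nifHRc	TGGGCYTTGTTYTCRCGGATYGGCAT	reverse	412	437	universal	Roesch-a	16	69.1-74.2	0	0	
nifHRb	TGSGCYTTGTCYTCRCGGATBGGCAT	reverse	412	437	universal	Roesch-a	48	70.0-76.0	1	0	suspected single-base publication error
PicenoR436	SACGATGTAGATPTCCTG	reverse	436	453	universal	Piceno	4	NA	0	1	contains non-IUPAC P base code; excluded from matching and Tm
R6	TCIGGIGARATGATGGC	reverse	457	473	universal	Marusina	2	61.1-62.5	0	0	
polR	ATSGCCATCATYTCRCCGGA	reverse	457	476	universal	Poly	8	63.7-67.5	0	0	
nifH1	ADNGCCATCATYTCNCC	reverse	460	476	universal	Zehr-McReynolds	96	52.5-63.9	0	0	
nifH22	ADWGCCATCATYTCRCC	reverse	460	476	universal	Yeager	24	53.2-60.9	0	0	
nifH2-ZANI	ANDGCCATCATYTCNCC	reverse	460	476	universal	Zani	96	52.5-63.6	0	0	5' linker sequence removed; renamed to disambiguate
470	TANANNGCCATCATYTCNCC	reverse	460	479	universal	Poly	512	53.8-65.7	0	0	
nifH-univ-463r	GCRTAIABNGCCATCATYTC	reverse	463	482	universal	Widmer	48	55.7-63.8	0	0	
Emino	GCRTAIAIIGCCATCATYTC	reverse	463	482	universal	Poly	4	60.2-63.4	0	0	
nifHR-2	ATGATGGCSATGTAYGCSGCSAACAA	forward	466	491	universal	Roesch-a	16	70.0-71.7	0	0	reverse primer printed in sense-strand orientation; scanned as-is
nifHR	TTGTTSGCSGCRTACATSGCCATCAT	reverse	466	491	universal	Roesch-b	16	70.0-71.7	0	0	
nifH-3r	TTGTTGGCIGCRTASAKIGCCAT	reverse	469	491	universal	Fedorov	8	68.5-72.1	0	0	
nifH3	ATRTTRTTNGCNGCRTA	reverse	478	494	universal	Zani	128	46.1-61.5	0	0	binding window printed 494-478; normalized to 478-494
YAA-poly	YAAATRTTRTTNGCNGCRTA	reverse	478	497	universal	Poly	256	49.5-63.5	1	0	suspected publication error: name fragment YAA prepended to sequence
RL25	CAGATCAGVCCGCCSAGRCGMAC	reverse	532	554	universal	Bagwell	24	67.5-74.1	0	0	
primer-r	GGCACGAAGTGGATCAGCTG	reverse	619	638	universal	Flores-Mireles	1	64.3	0	0	
AMR-R	GCTACTACYTCGCCSGA	reverse	NA	NA	universal	Roesch-b	NA	NA	1	0	does not match nifH; appears to be erroneous; no binding window
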