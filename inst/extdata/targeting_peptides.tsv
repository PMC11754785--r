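gene	uniprot_id	araport_id	start	sequence	thylakoid_lumen	protein_ratio	peptide_ratio
PSBQ2	Q41932	AT4G05180	62	SVIGLVAAGLAGGSFVK	TRUE	-1.50	4.14
PSAF	Q9SHE8	AT1G31330	47	AFSAAVALSSILLSAPMPAVADISGLTPCK	TRUE	-1.19	3.83
PSBQ2	Q41932	AT4G05180	79	AVFAEAIPIK	TRUE	-1.50	3.31
PSBP1	Q42029	AT1G06680	57	LALTLLVGAAAVGSK	TRUE	-0.80	3.76
PSBP1	Q42029	AT1G06680	72	VSPADAAYGEAANVFGK	TRUE	-0.80	3.73
PSBP1	Q42029	AT1G06680	72	VSPADAAYGEAANVFGKPK	TRUE	-0.80	3.64
PSBO1	P23321	AT5G66570	68	IAGFALATSALVVSGASAEGAPK	TRUE	-0.82	3.55
PSBO2	Q9S841	AT3G50820	67	IAGFALATSALVVSGAGAEGAPK	TRUE	-0.92	3.41
PSAN	P49107	AT5G64040	27	VGLVNSSVGFGQK	TRUE	-0.92	2.74
PDE334	Q42139	AT4G32260	50	ALSLSSATAK	FALSE	-0.58	2.86
CA1	A0A1I9LQB3	AT3G01500	16	LLIEKEELK	FALSE	-0.58	2.59
PSBO1	P23321	AT5G66570	37	SFGLETSSAR	TRUE	-0.82	2.30
LHCB5	Q9XF89	AT4G10340	22	SSAPLASSPSTFK	FALSE	-0.92	1.69
LHCB4.1	Q07473	AT5G01530	30	FTAVFGFGK	FALSE	-0.95	1.51
FKBP13	Q9SCY2	AT5G45680	42	VSSDPELSFAQLSSCGR	TRUE	-0.91	1.47
LHCA1	Q01667	AT3G54890	26	FVSAGVPLPNAGNVGR	FALSE	-0.89	1.37
CFBP1	P25851	AT3G54050	2	AATAATTTSSHLLLSSSR	FALSE	-0.60	1.40
ATPC1	Q01908	AT4G04640	43	ASSVSPLQASLR	FALSE	-0.91	0.94
LHB1B2	Q39141	AT2G34420	17	AVKPAASDVLGSGR	FALSE	-1.55	0.31
LHCB1.2	Q8VZ87	AT1G29920	2	AASTMALSSPAFAGK	FALSE	-1.03	0.67
CAS	Q9FN48	AT5G23060	31	QVSVSLPTSTSISLLSLFASPPHEAK	FALSE	-1.30	0.34
LHCB3	Q9S7M0	AT5G54270	40	YTMGNDLWYGPDR	FALSE	-1.15	0.19
LHCB6	Q9LMQ2	AT1G15820	43	TLIVAAAAAQPK	FALSE	-1.06	0.21
F13M23.70	Q9SW33	AT4G24930	20	LLCSLQSPK	TRUE	-1.03	0.10
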