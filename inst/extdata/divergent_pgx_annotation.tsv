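variant_id	rsid	gene	drugs	evidence_level	association_type	mode_of_effect	effect_allele
chr1:97883329:A:G	rs1801265	DPYD	capecitabine, fluorouracil	1A	toxicity	unknown	G
chr4:88131171:G:T	rs2231142	ABCG2	rosuvastatin	1A	dosage	unknown	T
chr19:15879621:C:T	rs2108622	CYP4F2	warfarin	1A	dosage	unknown	T
chr19:39248147:C:T	rs12979860	IFNL3, IFNL4	peginterferon alfa-2a, peginterferon alfa-2b, ribavirin, telaprevir, boceprevir	1A	efficacy	unknown	T
chr16:31093557:G:A	rs9934438	VKORC1	warfarin	1B	dosage	unknown	A
chr16:31096368:C:T	rs9923231	VKORC1	warfarin	1B	toxicity	dominant	T
chr19:39252525:T:G	rs8099917	IFNL3	interferons, peginterferon alfa-2a, peginterferon alfa-2b, ribavirin	1B	efficacy	unknown	G
chr16:31091000:C:T	rs7294	VKORC1	warfarin	1B	dosage	unknown	T
chr1:11796321:G:A	rs1801133	MTHFR	methotrexate	2A	toxicity	dominant	A
chr7:99767460:G:A	rs4646437	CYP3A4	tacrolimus	2A	toxicity	dominant	A
chr21:45537880:T:C	rs1051266	SLC19A1	methotrexate	2A	toxicity	unknown	C
chr12:21178615:T:C	rs4149056	SLCO1B1	hmg coa reductase inhibitors	2A	toxicity	unknown	C
chr12:111803962:G:A	rs671	ALDH2	ethanol	2B	toxicity	unknown	A
chr6:39357302:A:G	rs20455	KIF6	pravastatin	2B	efficacy	unknown	G
chr2:166053034:C:T	rs3812718	SCN1A	carbamazepine	2B	dosage	unknown	T
chr15:78590583:G:A	rs16969968	CHRNA5	nicotine	2B	other	unknown	A
chr15:74720644:T:C	rs1048943	CYP1A1	capecitabine, docetaxel	3	toxicity	unknown	C
chr16:31087690:T:C	rs11150606	VKORC1	warfarin	3	dosage	unknown	C
chr2:101806532:T:C	rs4550690	MAP4K4	anastrozole, exemestane	3	other	unknown	C
chr8:42298528:A:G	rs9694958	IKBKB	gefitinib	3	toxicity	recessive	A
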