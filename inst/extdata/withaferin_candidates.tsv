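symbol	compare_r	id_no	genbank	cluster
CORO1A	0.65	GC9728	AA047478	1
LSM2	0.646	GC31813	AJ245416	1
HCLS1	0.676	GC34797	X16663	1
unknown	0.643	GC34785	X79234	2
PLS3	-0.606	GC37799	M22299	2
RAD54L	0.654	GC32858	X97795	2
RPL5	0.648	GC36655	U14966	2
IKZF1	0.648	GC61547	AI247840	2
DLG2	-0.612	GC10718	R41930	2
RPS23	0.669	GC37806	D14530	2
unknown	0.674	GC33814	D11327	2
RNF138	0.688	GC67595	AI608790	2
unknown	0.663	GC31615	X79234	2
LCP1	0.649	GC27422	J02923	2
LAMB1	-0.610	GC18026	AA004918	2
SH3BP4	-0.608	GC16071	W72796	2
UACA	-0.624	GC14684	N66980	2
BCAR3	-0.636	GC14433	N48319	2
ZNF112	-0.640	GC15668	W15410	2
LOC440055	0.721	GC36107	AA977163	2
unknown	-0.601	GC14769	N92652	2
ALDH7A1	-0.642	GC16889	AA024918	2
ADAM9	-0.611	GC15762	W47533	2
TRIM3	-0.616	GC14991	N71362	2
ITGB1	-0.638	GC19072	AA044261	2
RGS12	-0.639	GC15931	W67134	2
TJP1	-0.612	GC12455	R79560	2
ASAP2	-0.638	GC15131	N70773	2
STMN4	-0.650	GC11515	H29581	2
WAS	0.654	GC69113	AI655719	2
NACA	0.652	GC30164	AF054187	2
NASP	0.657	GC83792	AW003362	2
LOC729362	0.679	GC31589	T89651	2
GNA11	-0.639	GC31915	N36926	2
unknown	-0.658	GC32458	M69013	2
CD53	0.666	GC89937	M37033	3
PPIH	0.662	GC28763	AF016371	3
PTPN7	0.707	GC90165	M64322	3
ANXA2P3	-0.652	GC90123	M62895	3
ANXA2	-0.659	GC85483	D00017	3
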