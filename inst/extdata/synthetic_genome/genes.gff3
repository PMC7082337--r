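##gff-version 3
ctg1	mnAOM	CDS	1	1095	.	+	0	ID=sim_0001;product=multiheme cytochrome
ctg1	mnAOM	CDS	1196	2095	.	+	0	ID=sim_oxr001;product=b-type cytochrome
ctg1	mnAOM	CDS	2196	3113	.	+	0	ID=sim_0002;product=multiheme cytochrome
ctg1	mnAOM	CDS	3214	4113	.	+	0	ID=sim_oxr002;product=b-type cytochrome
ctg1	mnAOM	CDS	4214	5398	.	+	0	ID=sim_0003;product=multiheme cytochrome
ctg1	mnAOM	CDS	5499	6398	.	+	0	ID=sim_oxr003;product=b-type cytochrome
ctg2	mnAOM	CDS	6499	7194	.	+	0	ID=sim_0004;product=multiheme cytochrome
ctg2	mnAOM	CDS	7295	8389	.	+	0	ID=sim_0005;product=multiheme cytochrome
ctg2	mnAOM	CDS	8490	9641	.	+	0	ID=sim_0006;product=multiheme cytochrome
ctg2	mnAOM	CDS	9742	10545	.	+	0	ID=sim_0007;product=hypothetical
ctg2	mnAOM	CDS	10646	11824	.	+	0	ID=sim_0008;product=hypothetical
ctg2	mnAOM	CDS	11925	12665	.	+	0	ID=sim_0009;product=hypothetical
ctg2	mnAOM	CDS	12766	13647	.	+	0	ID=sim_0010;product=hypothetical
ctg2	mnAOM	CDS	13748	14689	.	+	0	ID=sim_0011;product=hypothetical
ctg2	mnAOM	CDS	14790	15650	.	+	0	ID=sim_0012;product=hypothetical
ctg2	mnAOM	CDS	15751	16824	.	+	0	ID=sim_0013;product=hypothetical
ctg2	mnAOM	CDS	16925	17899	.	+	0	ID=sim_0014;product=hypothetical
ctg2	mnAOM	CDS	18000	19133	.	+	0	ID=sim_0015;product=hypothetical
ctg2	mnAOM	CDS	19234	20250	.	+	0	ID=sim_0016;product=hypothetical
ctg2	mnAOM	CDS	20351	21118	.	+	0	ID=sim_0017;product=hypothetical
ctg2	mnAOM	CDS	21219	22043	.	+	0	ID=sim_0018;product=hypothetical
ctg2	mnAOM	CDS	22144	23001	.	+	0	ID=sim_0019;product=hypothetical
ctg2	mnAOM	CDS	23102	23743	.	+	0	ID=sim_0020;product=hypothetical
ctg2	mnAOM	CDS	23844	24770	.	+	0	ID=sim_0021;product=hypothetical
ctg2	mnAOM	CDS	24871	25476	.	+	0	ID=sim_0022;product=hypothetical
ctg2	mnAOM	CDS	25577	26221	.	+	0	ID=sim_0023;product=hypothetical
ctg2	mnAOM	CDS	26322	27515	.	+	0	ID=sim_0024;product=hypothetical
ctg2	mnAOM	CDS	27616	28614	.	+	0	ID=sim_0025;product=hypothetical
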