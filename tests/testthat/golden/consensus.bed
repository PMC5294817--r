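chr1	80	440	setB	0	.
chr1	489	815	setA	0	.
chr1	2567	2826	setA	0	.
chr1	5096	5419	setA	0	.
chr1	7514	7918	setA	0	.
chr1	16854	17141	setB	0	.
chr1	17156	17435	setB	0	.
chr1	20177	20372	setA	0	.
chr1	23716	24050	setB	0	.
chr1	26815	27175	setB	0	.
chr1	27288	27616	setA	0	.
chr1	29164	29557	setB	0	.
chr1	31936	32161	setA	0	.
chr1	34967	35185	setA	0	.
chr1	36178	36585	setA	0	.
chr1	36979	37280	setB	0	.
chr1	40003	40523	setB	0	.
chr1	44830	45183	setA	0	.
chr1	46778	47114	setA	0	.
chr1	48383	48740	setA	0	.
chr1	49069	49385	setB	0	.
chr1	52124	52457	setB	0	.
chr1	54815	55135	setB	0	.
chr1	57284	57601	setB	0	.
chr1	58108	58371	setB	0	.
chr1	59555	59886	setB	0	.
chr1	60445	60777	setA	0	.
chr1	61730	62339	setB	0	.
chr1	62622	62813	setA	0	.
chr1	63118	63438	setB	0	.
chr1	63941	64239	setA	0	.
chr1	64291	64638	setA	0	.
chr1	64784	65073	setB	0	.
chr1	65192	65440	setA	0	.
chr1	65880	66200	setB	0	.
chr1	66586	66893	setB	0	.
chr1	67476	67857	setB	0	.
chr1	68073	68731	setA,setB	0	.
chr1	72540	72865	setB	0	.
chr1	75550	75825	setA	0	.
chr1	82263	82559	setA	0	.
chr1	82778	83052	setA	0	.
chr1	84301	84666	setA	0	.
chr1	85037	85292	setB	0	.
chr1	86136	86401	setA	0	.
chr1	86531	86807	setB	0	.
chr1	88111	88315	setA	0	.
chr1	89143	89471	setB	0	.
chr1	94466	94795	setA	0	.
chr1	99088	99513	setA	0	.
chr1	99863	100108	setA	0	.
chr1	106169	106449	setA	0	.
chr1	106660	106943	setA	0	.
chr1	107368	107661	setB	0	.
chr1	111122	111373	setB	0	.
chr1	111842	112236	setB	0	.
chr1	112687	112985	setB	0	.
chr1	119450	119949	setA,setB	0	.
chr1	127234	127661	setB	0	.
chr1	131870	132162	setA	0	.
chr1	141715	141881	setB	0	.
chr1	155640	156011	setB	0	.
chr1	160336	160575	setA	0	.
chr1	161464	161664	setB	0	.
chr1	162171	162474	setB	0	.
chr1	163837	164129	setA	0	.
chr1	175857	176110	setB	0	.
chr1	179735	180040	setB	0	.
chr1	180202	180415	setB	0	.
chr1	191427	191758	setA	0	.
chr1	194375	194662	setB	0	.
chr1	195053	195402	setA	0	.
chr1	196350	196855	setA,setB	0	.
chr1	197339	197570	setA	0	.
chr1	199370	199757	setB	0	.
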