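trait	peak_set	N	K	n	k	p_raw	p_under	m	p_corrected	snps_under_peaks
planted_trait	combined	87	32	24	18	8.72827238439875e-06	0.999999247774771	10	8.72827238439875e-05	rsim1_1/rsim1_10,rsim1_2/rsim1_10,rsim1_4/rsim1_10,rsim1_8/rsim1_10,rsim3_1/rsim3_3,rsim3_10/rsim3_3,rsim3_5/rsim3_3,rsim3_9/rsim3_3,rsim7_1/rsim7_8,rsim7_10/rsim7_8,rsim7_2/rsim7_8,rsim7_3/rsim7_8,rsim7_7/rsim7_8,rsim7_8/rsim7_8,rsim7_9/rsim7_8,rsim9_3/rsim9_4,rsim9_4/rsim9_4,rsim9_8/rsim9_4
planted_trait	setA	87	32	11	10	0.000131303834791859	0.999995392847901	8	0.00105043067833487	rsim1_2/rsim1_10,rsim1_4/rsim1_10,rsim1_8/rsim1_10,rsim3_1/rsim3_3,rsim7_1/rsim7_8,rsim7_10/rsim7_8,rsim7_3/rsim7_8,rsim7_7/rsim7_8,rsim9_3/rsim9_4,rsim9_4/rsim9_4
trait_005	combined	87	24	24	13	0.00106319290237297	0.999833873188395	10	0.0106319290237297	rsim3_1/rsim3_1,rsim3_10/rsim3_1,rsim5_1/rsim5_1,rsim7_1/rsim7_7,rsim7_10/rsim7_7,rsim7_2/rsim7_7,rsim7_3/rsim7_7,rsim7_5/rsim7_7,rsim7_7/rsim7_7,rsim7_8/rsim7_7,rsim7_9/rsim7_7,rsim9_3/rsim9_1,rsim9_8/rsim9_1
trait_002	combined	87	24	24	12	0.00527441982848982	0.998936807097624	10	0.0527441982848982	rsim3_1/rsim3_4,rsim3_10/rsim3_4,rsim3_5/rsim3_7,rsim3_9/rsim3_7,rsim7_1/rsim7_1,rsim7_10/rsim7_1,rsim7_2/rsim7_1,rsim7_3/rsim7_1,rsim7_5/rsim7_1,rsim7_7/rsim7_1,rsim7_8/rsim7_1,rsim7_9/rsim7_1
trait_005	setA	87	24	11	7	0.00850011610084544	0.998861431655327	8	0.0680009288067635	rsim3_1/rsim3_1,rsim7_1/rsim7_7,rsim7_10/rsim7_7,rsim7_3/rsim7_7,rsim7_5/rsim7_7,rsim7_7/rsim7_7,rsim9_3/rsim9_1
planted_trait	setB	87	32	14	9	0.0227997403105931	0.995240626744766	10	0.227997403105931	rsim1_1/rsim1_10,rsim3_10/rsim3_3,rsim3_5/rsim3_3,rsim3_9/rsim3_3,rsim7_10/rsim7_8,rsim7_2/rsim7_8,rsim7_8/rsim7_8,rsim7_9/rsim7_8,rsim9_8/rsim9_4
trait_002	setA	87	24	11	6	0.0422814408041836	0.991499883899152	8	0.338251526433469	rsim3_1/rsim3_4,rsim7_1/rsim7_1,rsim7_10/rsim7_1,rsim7_3/rsim7_1,rsim7_5/rsim7_1,rsim7_7/rsim7_1
trait_002	setB	87	24	14	7	0.0465775246541827	0.98882634707352	10	0.465775246541827	rsim3_10/rsim3_4,rsim3_5/rsim3_7,rsim3_9/rsim3_7,rsim7_10/rsim7_1,rsim7_2/rsim7_1,rsim7_8/rsim7_1,rsim7_9/rsim7_1
trait_005	setB	87	24	14	7	0.0465775246541827	0.98882634707352	10	0.465775246541827	rsim3_10/rsim3_1,rsim5_1/rsim5_1,rsim7_10/rsim7_7,rsim7_2/rsim7_7,rsim7_8/rsim7_7,rsim7_9/rsim7_7,rsim9_8/rsim9_1
trait_003	combined	87	24	24	10	0.0633182573955864	0.97947545662841	10	0.633182573955864	rsim2_6/rsim2_8,rsim2_7/rsim2_8,rsim7_1/rsim7_10,rsim7_10/rsim7_10,rsim7_2/rsim7_10,rsim7_3/rsim7_10,rsim7_5/rsim7_10,rsim7_7/rsim7_10,rsim7_8/rsim7_10,rsim7_9/rsim7_10
trait_003	setB	87	24	14	6	0.142954731024032	0.953422475345821	10	1	rsim2_6/rsim2_8,rsim2_7/rsim2_8,rsim7_10/rsim7_10,rsim7_2/rsim7_10,rsim7_8/rsim7_10,rsim7_9/rsim7_10
trait_003	setA	87	24	11	5	0.145403379372269	0.957718559195814	8	1	rsim7_1/rsim7_10,rsim7_10/rsim7_10,rsim7_3/rsim7_10,rsim7_5/rsim7_10,rsim7_7/rsim7_10
trait_001	combined	87	15	24	5	0.397737059807574	0.808636626507086	10	1	rsim3_5/rsim3_5,rsim9_3/rsim9_7,rsim9_4/rsim9_8,rsim9_7/rsim9_7,rsim9_8/rsim9_7
trait_009	setB	87	14	14	3	0.399004468352448	0.840478440109878	10	1	rsim2_6/rsim2_6,rsim2_7/rsim2_6,rsim9_8/rsim9_5
trait_001	setB	87	15	14	3	0.449853579053352	0.804391974451174	10	1	rsim3_5/rsim3_5,rsim9_7/rsim9_7,rsim9_8/rsim9_7
trait_009	combined	87	14	24	4	0.5800338160522	0.671054168963975	10	1	rsim2_6/rsim2_6,rsim2_7/rsim2_6,rsim9_3/rsim9_5,rsim9_8/rsim9_5
trait_001	setA	87	15	11	2	0.604879030565445	0.714234821400784	8	1	rsim9_3/rsim9_7,rsim9_4/rsim9_8
trait_004	setA	87	28	11	3	0.757585177474042	0.501810271780503	8	1	rsim3_1/rsim3_2,rsim9_3/rsim9_2,rsim9_4/rsim9_2
trait_006	setB	87	24	14	3	0.810469542560568	0.419966183947795	10	1	rsim2_6/rsim2_7,rsim2_7/rsim2_7,rsim6_10/rsim6_4
trait_007	setA	87	31	11	3	0.82947679918897	0.398520422723512	8	1	rsim1_2/rsim1_9,rsim1_4/rsim1_9,rsim1_8/rsim1_9
trait_009	setA	87	14	11	1	0.87293466621708	0.437669483030049	8	1	rsim9_3/rsim9_5
trait_004	combined	87	28	24	6	0.874314209026681	0.268055428410427	10	1	rsim3_1/rsim3_2,rsim3_10/rsim3_2,rsim6_10/rsim6_2,rsim9_3/rsim9_2,rsim9_4/rsim9_2,rsim9_8/rsim9_2
trait_004	setB	87	28	14	3	0.898350731983839	0.271164792304645	10	1	rsim3_10/rsim3_2,rsim6_10/rsim6_2,rsim9_8/rsim9_2
trait_007	combined	87	31	24	6	0.939289717063858	0.15194766878625	10	1	rsim1_1/rsim1_9,rsim1_2/rsim1_9,rsim1_4/rsim1_9,rsim1_8/rsim1_9,rsim2_7/rsim2_9,rsim6_10/rsim6_9
trait_007	setB	87	31	14	3	0.940089151651608	0.183658608327033	10	1	rsim1_1/rsim1_9,rsim2_7/rsim2_9,rsim6_10/rsim6_9
trait_008	setB	87	22	14	1	0.988723265783523	0.0780696984218048	10	1	rsim6_10/rsim6_7
trait_006	combined	87	24	24	3	0.990098822554219	0.0425259352560119	10	1	rsim2_6/rsim2_7,rsim2_7/rsim2_7,rsim6_10/rsim6_4
trait_008	combined	87	22	24	1	0.999768090974647	0.00314733677261304	10	1	rsim6_10/rsim6_7
trait_006	setA	87	24	11	0	1	0.0219883806051796	8	1	/
trait_008	setA	87	22	11	0	1	0.0319607488880319	8	1	/
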