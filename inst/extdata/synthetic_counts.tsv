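#OTU ID	s001	s002	s003	s004	s005	s006	s007	s008	s009	s010	s011	s012	s013	s014	s015	s016	s017	s018	s019	s020	taxonomy
otu001	323	680	120	109	292	208	223	68	149	188	18	137	15	85	21	45	25	266	30	244	k__Bacteria; p__Tenericutes
otu002	7	3	2	1	2	0	17	0	2	1	0	1	2	5	13	11	0	4	2	3	k__Bacteria; p__Bacteroidetes
otu003	345	529	549	118	238	276	167	305	580	122	341	130	62	248	61	277	1032	126	53	156	k__Bacteria; p__Firmicutes
otu004	0	0	3	1	0	0	2	0	4	1	0	0	0	0	0	0	1	0	4	0	k__Bacteria; p__Verrucomicrobia
otu005	5	1	4	1	6	1	2	1	14	0	0	1	7	0	5	5	1	7	0	9	k__Bacteria; p__Firmicutes
otu006	39	6	14	21	64	39	20	40	34	17	13	47	68	226	136	69	102	236	45	17	k__Bacteria; p__Proteobacteria
otu007	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	k__Bacteria; p__Firmicutes
otu008	1	2	4	0	2	0	1	1	0	3	2	1	1	0	1	1	0	1	0	0	k__Bacteria; p__Tenericutes
otu009	4	0	2	6	14	0	41	3	2	0	6	0	0	4	2	11	1	7	6	3	k__Bacteria; p__Actinobacteria
otu010	45	0	0	0	3	2	2	0	1	0	0	3	5	1	7	3	0	3	4	2	k__Bacteria; p__Firmicutes
otu011	3	4	8	6	1	13	8	2	3	1	8	4	9	6	11	1	7	6	32	2	k__Bacteria; p__Firmicutes
otu012	1	3	0	10	15	30	1	0	1	1	8	1	7	2	18	2	3	10	5	14	k__Bacteria; p__Bacteroidetes
otu013	10	1	0	0	1	2	2	2	4	1	4	0	0	0	2	0	0	1	2	15	k__Bacteria; p__Tenericutes
otu014	38	123	48	230	186	58	34	8	164	24	23	36	25	66	25	127	49	83	161	204	k__Bacteria; p__Bacteroidetes
otu015	0	0	2	0	0	1	2	0	1	0	1	0	0	0	0	0	0	3	0	2	k__Bacteria; p__Actinobacteria
otu016	0	2	7	3	0	0	4	0	3	0	2	12	7	0	3	0	3	2	1	2	k__Bacteria; p__Tenericutes
otu017	490	268	66	226	114	90	208	20	53	76	72	25	18	24	13	8	7	41	8	28	k__Bacteria; p__Firmicutes
otu018	32	17	3	8	2	1	3	2	21	1	4	3	0	3	3	1	8	19	4	1	k__Bacteria; p__Tenericutes
otu019	5	5	8	10	6	1	3	3	4	6	28	82	99	19	41	32	7	8	18	8	k__Bacteria; p__Tenericutes
otu020	12	7	15	8	20	5	6	3	74	21	14	21	33	11	22	27	15	8	8	4	k__Bacteria; p__Verrucomicrobia
otu021	4	13	25	2	2	28	8	6	19	7	13	3	0	11	8	0	7	4	32	3	k__Bacteria; p__Firmicutes
otu022	15	18	8	9	33	5	9	141	28	2	55	2	11	2	6	3	1	16	10	2	k__Bacteria; p__Verrucomicrobia
otu023	0	11	29	10	15	26	134	7	3	14	140	50	7	26	28	136	253	141	711	56	k__Bacteria; p__Proteobacteria
otu024	9	6	8	54	14	16	12	5	20	8	8	21	38	19	30	31	19	4	19	3	k__Bacteria; p__Firmicutes
otu025	11	3	25	5	1	2	3	0	1	1	0	0	13	4	4	0	19	13	9	15	k__Bacteria; p__Firmicutes
otu026	1	0	0	0	0	0	0	0	6	0	2	0	0	0	0	1	0	6	1	0	k__Bacteria; p__Tenericutes
otu027	1	1	8	1	1	2	0	7	1	0	3	1	1	0	1	0	1	8	0	1	k__Bacteria; p__Verrucomicrobia
otu028	0	0	0	2	0	2	0	0	0	0	0	0	1	0	2	0	1	1	0	4	k__Bacteria; p__Verrucomicrobia
otu029	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	k__Bacteria; p__Proteobacteria
otu030	6	0	0	5	0	1	5	0	0	0	6	1	0	0	5	17	0	3	6	7	k__Bacteria; p__Actinobacteria
otu031	5	4	5	25	1	1	7	3	1	2	37	0	1	1	3	1	12	8	8	17	k__Bacteria; p__Bacteroidetes
otu032	236	75	187	565	413	659	647	1013	308	1140	220	25	51	8	132	51	68	231	51	437	k__Bacteria; p__Tenericutes
otu033	179	82	580	266	179	37	136	134	209	248	726	1310	1405	1082	965	913	262	478	537	336	k__Bacteria; p__Proteobacteria
otu034	72	46	15	49	16	65	50	15	138	55	8	59	64	6	256	138	45	36	189	216	k__Bacteria; p__Actinobacteria
otu035	1	0	1	0	0	0	3	0	0	0	2	4	1	0	0	1	0	1	2	0	k__Bacteria; p__Proteobacteria
otu036	0	0	0	0	0	0	0	0	0	0	1	0	1	0	2	0	1	0	0	1	k__Bacteria; p__Firmicutes
otu037	1	2	2	1	2	4	0	3	4	4	0	0	2	1	0	0	5	0	2	2	k__Bacteria; p__Bacteroidetes
otu038	23	16	183	81	209	290	36	8	83	39	79	5	28	130	144	58	17	186	25	124	k__Bacteria; p__Proteobacteria
otu039	46	63	5	68	93	21	55	10	62	0	4	12	13	3	23	1	8	8	9	38	k__Bacteria; p__Firmicutes
otu040	30	9	64	99	55	114	149	190	3	17	151	3	5	7	7	29	20	25	6	24	k__Bacteria; p__Verrucomicrobia
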