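T:cytochemokine_response_01	T:cytochemokine_response_01	Gene0001	Gene0125	Gene0141	Gene0149	Gene0151	Gene0153	Gene0156	Gene0158	Gene0160	Gene0162	Gene0164	Gene0168	Gene0170	Gene0171	Gene0175	Gene0223	Gene0258	Gene0343
T:cytochemokine_response_02	T:cytochemokine_response_02	Gene0049	Gene0086	Gene0141	Gene0143	Gene0145	Gene0146	Gene0149	Gene0151	Gene0156	Gene0158	Gene0160	Gene0162	Gene0164	Gene0170	Gene0171	Gene0175	Gene0358	Gene0394
T:cytochemokine_response_03	T:cytochemokine_response_03	Gene0143	Gene0145	Gene0153	Gene0156	Gene0158	Gene0160	Gene0162	Gene0164	Gene0166	Gene0168	Gene0170	Gene0171	Gene0175	Gene0180	Gene0210	Gene0297	Gene0323	Gene0329
T:gliogenesis_01	T:gliogenesis_01	Gene0114	Gene0144	Gene0146	Gene0150	Gene0152	Gene0154	Gene0157	Gene0163	Gene0165	Gene0167	Gene0169	Gene0172	Gene0174	Gene0247	Gene0273	Gene0303
T:gliogenesis_02	T:gliogenesis_02	Gene0046	Gene0142	Gene0146	Gene0148	Gene0150	Gene0154	Gene0161	Gene0165	Gene0167	Gene0169	Gene0172	Gene0174	Gene0244	Gene0249	Gene0342	Gene0388
T:gliogenesis_03	T:gliogenesis_03	Gene0115	Gene0117	Gene0142	Gene0146	Gene0148	Gene0154	Gene0157	Gene0159	Gene0161	Gene0165	Gene0167	Gene0172	Gene0174	Gene0188	Gene0309	Gene0316
T:noise_01	T:noise_01	Cd3e	Gene0011	Gene0046	Gene0077	Gene0090	Gene0095	Gene0112	Gene0135	Gene0198	Gene0208	Gene0216	Gene0220	Gene0228	Gene0255	Gene0265	Gene0277	Gene0290	Gene0292	Gene0306	Gene0313	Gene0320	Gene0350	Gene0356	Gene0358	Gene0384
T:noise_02	T:noise_02	Gene0006	Gene0018	Gene0047	Gene0067	Gene0068	Gene0070	Gene0071	Gene0077	Gene0139	Gene0143	Gene0146	Gene0160	Gene0199	Gene0222	Gene0245	Gene0262	Gene0264	Gene0299	Gene0332	Gene0337	Gene0348	Gene0360	Gene0377	Gene0378	Gene0391
T:noise_03	T:noise_03	Gene0006	Gene0013	Gene0014	Gene0017	Gene0034	Gene0090	Gene0095	Gene0129	Gene0150	Gene0160	Gene0198	Gene0204	Gene0210	Gene0212	Gene0213	Gene0219	Gene0234	Gene0236	Gene0292	Gene0317	Gene0334	Gene0339	Gene0346	Gene0372	Gene0397
T:noise_04	T:noise_04	Gene0025	Gene0029	Gene0033	Gene0045	Gene0047	Gene0049	Gene0079	Gene0084	Gene0121	Gene0152	Gene0197	Gene0203	Gene0205	Gene0222	Gene0239	Gene0248	Gene0258	Gene0286	Gene0293	Gene0314	Gene0317	Gene0325	Gene0346	Gene0371	Gene0375
T:noise_05	T:noise_05	Gene0012	Gene0049	Gene0057	Gene0059	Gene0064	Gene0066	Gene0123	Gene0137	Gene0144	Gene0153	Gene0156	Gene0185	Gene0196	Gene0212	Gene0228	Gene0231	Gene0241	Gene0259	Gene0307	Gene0313	Gene0314	Gene0342	Gene0349	Gene0360	Gene0388
T:noise_06	T:noise_06	Gene0011	Gene0018	Gene0049	Gene0051	Gene0058	Gene0061	Gene0075	Gene0127	Gene0143	Gene0152	Gene0171	Gene0175	Gene0193	Gene0218	Gene0219	Gene0248	Gene0274	Gene0296	Gene0299	Gene0302	Gene0303	Gene0343	Gene0367	Gene0369	Gene0388
T:noise_07	T:noise_07	Gene0006	Gene0024	Gene0040	Gene0077	Gene0089	Gene0090	Gene0110	Gene0111	Gene0133	Gene0147	Gene0152	Gene0185	Gene0197	Gene0208	Gene0211	Gene0217	Gene0244	Gene0271	Gene0294	Gene0329	Gene0338	Gene0345	Gene0361	Gene0379	Gene0392
T:noise_08	T:noise_08	Gene0007	Gene0020	Gene0024	Gene0027	Gene0031	Gene0033	Gene0045	Gene0079	Gene0098	Gene0115	Gene0196	Gene0201	Gene0224	Gene0247	Gene0268	Gene0292	Gene0303	Gene0339	Gene0344	Gene0351	Gene0367	Gene0385	Gene0388	Gene0392	Gene0395
T:noise_09	T:noise_09	Cd4	Gene0006	Gene0024	Gene0050	Gene0086	Gene0107	Gene0117	Gene0122	Gene0123	Gene0147	Gene0168	Gene0206	Gene0218	Gene0219	Gene0235	Gene0251	Gene0259	Gene0268	Gene0291	Gene0294	Gene0302	Gene0312	Gene0331	Gene0339	Gene0374
T:noise_10	T:noise_10	Cd3e	Gene0007	Gene0019	Gene0031	Gene0041	Gene0046	Gene0061	Gene0064	Gene0121	Gene0184	Gene0191	Gene0193	Gene0198	Gene0204	Gene0220	Gene0221	Gene0230	Gene0243	Gene0258	Gene0305	Gene0323	Gene0353	Gene0364	Gene0374	Gene0375
T:noise_11	T:noise_11	Cd3e	Gene0018	Gene0079	Gene0083	Gene0094	Gene0125	Gene0141	Gene0145	Gene0175	Gene0177	Gene0212	Gene0249	Gene0251	Gene0256	Gene0260	Gene0264	Gene0271	Gene0295	Gene0327	Gene0328	Gene0336	Gene0341	Gene0368	Gene0377	Gene0388
T:noise_12	T:noise_12	Gene0033	Gene0059	Gene0069	Gene0071	Gene0078	Gene0095	Gene0128	Gene0159	Gene0164	Gene0177	Gene0180	Gene0197	Gene0202	Gene0222	Gene0227	Gene0245	Gene0251	Gene0254	Gene0257	Gene0258	Gene0271	Gene0287	Gene0289	Gene0295	Gene0385
T:noise_13	T:noise_13	Gene0009	Gene0012	Gene0038	Gene0071	Gene0078	Gene0080	Gene0126	Gene0150	Gene0171	Gene0180	Gene0187	Gene0211	Gene0219	Gene0267	Gene0275	Gene0282	Gene0294	Gene0295	Gene0305	Gene0310	Gene0327	Gene0338	Gene0354	Gene0361	Gene0376
T:noise_14	T:noise_14	Gene0015	Gene0061	Gene0075	Gene0097	Gene0101	Gene0111	Gene0118	Gene0138	Gene0152	Gene0154	Gene0162	Gene0170	Gene0176	Gene0177	Gene0206	Gene0221	Gene0233	Gene0280	Gene0287	Gene0293	Gene0324	Gene0329	Gene0337	Gene0345	Gene0360
T:noise_15	T:noise_15	Gene0049	Gene0057	Gene0076	Gene0077	Gene0078	Gene0121	Gene0135	Gene0184	Gene0186	Gene0199	Gene0227	Gene0231	Gene0235	Gene0246	Gene0248	Gene0249	Gene0269	Gene0276	Gene0281	Gene0299	Gene0316	Gene0322	Gene0331	Gene0349	Gene0397
T:noise_16	T:noise_16	Cd3e	Gene0006	Gene0012	Gene0041	Gene0079	Gene0102	Gene0113	Gene0120	Gene0147	Gene0166	Gene0183	Gene0187	Gene0192	Gene0211	Gene0217	Gene0224	Gene0235	Gene0248	Gene0333	Gene0339	Gene0363	Gene0372	Gene0382	Gene0384	Gene0396
T:noise_17	T:noise_17	Gene0023	Gene0024	Gene0025	Gene0054	Gene0057	Gene0102	Gene0125	Gene0130	Gene0144	Gene0148	Gene0156	Gene0167	Gene0186	Gene0217	Gene0249	Gene0284	Gene0304	Gene0315	Gene0324	Gene0327	Gene0328	Gene0335	Gene0339	Gene0372	Gene0393
T:noise_18	T:noise_18	Gene0006	Gene0047	Gene0056	Gene0061	Gene0070	Gene0083	Gene0110	Gene0147	Gene0149	Gene0196	Gene0213	Gene0245	Gene0276	Gene0278	Gene0298	Gene0311	Gene0316	Gene0328	Gene0336	Gene0362	Gene0365	Gene0368	Gene0380	Gene0390	Gene0391
T:noise_19	T:noise_19	Gene0009	Gene0019	Gene0068	Gene0091	Gene0106	Gene0134	Gene0150	Gene0152	Gene0163	Gene0171	Gene0176	Gene0200	Gene0209	Gene0210	Gene0220	Gene0223	Gene0236	Gene0271	Gene0340	Gene0343	Gene0347	Gene0348	Gene0364	Gene0373	Gene0391
T:noise_20	T:noise_20	Gene0025	Gene0026	Gene0041	Gene0042	Gene0060	Gene0064	Gene0071	Gene0072	Gene0095	Gene0107	Gene0119	Gene0140	Gene0171	Gene0172	Gene0212	Gene0222	Gene0237	Gene0241	Gene0280	Gene0308	Gene0323	Gene0339	Gene0349	Gene0352	Gene0365
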