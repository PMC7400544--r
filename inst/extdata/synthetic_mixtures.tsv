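cpg_id	sample01	sample02	sample03	sample04	sample05
cg000001	0.6277	0.7219	0.8334	0.3209	0.8423
cg000002	0.629	0.7241	0.8334	0.7754	0.2225
cg000003	0.6276	0.7194	0.8365	0.316	0.8311
cg000004	0.6207	0.7201	0.5352	0.7721	0.8321
cg000005	0.6294	0.7273	0.8385	0.7703	0.8323
cg000006	0.6315	0.5718	0.5384	0.7711	0.8302
cg000007	0.6274	0.7209	0.8363	0.7703	0.8266
cg000008	0.6205	0.7192	0.5293	0.7738	0.8235
cg000009	0.6282	0.7208	0.8345	0.7724	0.8234
cg000010	0.6304	0.7226	0.8384	0.3247	0.8247
cg000011	0.6242	0.722	0.5363	0.7717	0.8332
cg000012	0.6316	0.7292	0.8404	0.3265	0.8342
cg000013	0.6339	0.7248	0.8336	0.7771	0.8333
cg000014	0.6291	0.5737	0.8434	0.769	0.8297
cg000015	0.6273	0.7176	0.8386	0.774	0.8233
cg000016	0.6305	0.7261	0.8373	0.7726	0.83
cg000017	0.6292	0.7208	0.8408	0.7749	0.8265
cg000018	0.6286	0.725	0.8416	0.7688	0.8384
cg000019	0.6221	0.7216	0.8356	0.7755	0.8315
cg000020	0.6275	0.5734	0.8386	0.7646	0.8361
cg000021	0.7379	0.7934	0.7895	0.2496	0.8116
cg000022	0.7433	0.7959	0.796	0.6989	0.815
cg000023	0.7449	0.7992	0.801	0.69	0.8125
cg000024	0.7483	0.801	0.8056	0.2497	0.2173
cg000025	0.7433	0.7987	0.8001	0.7035	0.8196
cg000026	0.7429	0.7942	0.4998	0.7019	0.213
cg000027	0.7434	0.7923	0.4982	0.6952	0.2081
cg000028	0.7428	0.7975	0.799	0.7063	0.814
cg000029	0.7343	0.7926	0.8011	0.6988	0.8094
cg000030	0.7459	0.7974	0.7983	0.2469	0.8111
cg000031	0.7476	0.7973	0.5017	0.7027	0.8135
cg000032	0.7405	0.7936	0.794	0.245	0.8082
cg000033	0.7442	0.7983	0.796	0.6982	0.8142
cg000034	0.7484	0.7968	0.8033	0.2503	0.2165
cg000035	0.7434	0.7988	0.7958	0.6981	0.8136
cg000036	0.7447	0.7971	0.7962	0.7012	0.8145
cg000037	0.7457	0.7936	0.5023	0.6958	0.2137
cg000038	0.7432	0.6439	0.5037	0.2527	0.807
cg000039	0.7402	0.797	0.4987	0.692	0.8118
cg000040	0.7426	0.7944	0.7992	0.2477	0.8164
cg000041	0.6863	0.635	0.6511	0.8119	0.8134
cg000042	0.691	0.6364	0.347	0.8058	0.8067
cg000043	0.6831	0.6329	0.6468	0.8044	0.8035
cg000044	0.6825	0.7862	0.6512	0.7981	0.7998
cg000045	0.6855	0.7829	0.6497	0.8043	0.8019
cg000046	0.685	0.7814	0.6455	0.3522	0.804
cg000047	0.6843	0.6321	0.6456	0.8093	0.8078
cg000048	0.6774	0.777	0.3435	0.8012	0.7985
cg000049	0.6914	0.6373	0.6566	0.8083	0.2037
cg000050	0.6857	0.7828	0.6486	0.8055	0.8032
cg000051	0.6861	0.7885	0.6512	0.7972	0.8059
cg000052	0.686	0.7891	0.6475	0.3595	0.8071
cg000053	0.6791	0.7763	0.6451	0.3466	0.8026
cg000054	0.679	0.6264	0.644	0.7984	0.2005
cg000055	0.6834	0.7792	0.6465	0.8142	0.2033
cg000056	0.6834	0.784	0.6491	0.8041	0.8064
cg000057	0.6875	0.7835	0.6496	0.8068	0.7911
cg000058	0.6812	0.781	0.6447	0.8028	0.2046
cg000059	0.6856	0.7803	0.6496	0.8033	0.7994
cg000060	0.6796	0.7801	0.6459	0.3478	0.8105
cg000061	0.7138	0.8249	0.8461	0.8423	0.8406
cg000062	0.7125	0.8232	0.8453	0.8465	0.8407
cg000063	0.7137	0.8252	0.8454	0.8496	0.2333
cg000064	0.7087	0.8222	0.8399	0.8499	0.2434
cg000065	0.708	0.8171	0.5371	0.8452	0.8422
cg000066	0.7165	0.8261	0.8394	0.8496	0.8393
cg000067	0.7125	0.8214	0.8418	0.844	0.8354
cg000068	0.7183	0.6747	0.8489	0.3972	0.8374
cg000069	0.7156	0.8292	0.8508	0.3995	0.846
cg000070	0.709	0.8242	0.5423	0.3984	0.843
cg000071	0.7167	0.676	0.8456	0.8552	0.8429
cg000072	0.7141	0.6733	0.8385	0.8556	0.8417
cg000073	0.7148	0.6782	0.843	0.8461	0.2386
cg000074	0.7185	0.8226	0.5483	0.4044	0.8391
cg000075	0.7153	0.6745	0.8447	0.4017	0.8431
cg000076	0.7151	0.8245	0.8492	0.8476	0.8342
cg000077	0.711	0.8209	0.8436	0.8534	0.8368
cg000078	0.714	0.671	0.5398	0.8469	0.8397
cg000079	0.7087	0.826	0.5402	0.8518	0.8415
cg000080	0.7049	0.8182	0.837	0.8407	0.234
cg000081	0.7888	0.7222	0.4191	0.833	0.2446
cg000082	0.78	0.7198	0.7108	0.8312	0.8518
cg000083	0.7912	0.727	0.7126	0.8308	0.8361
cg000084	0.7879	0.7258	0.7155	0.8291	0.2395
cg000085	0.7872	0.5725	0.4155	0.8303	0.8424
cg000086	0.794	0.7328	0.719	0.8373	0.8519
cg000087	0.7885	0.7281	0.4166	0.8325	0.8455
cg000088	0.7963	0.7333	0.72	0.3902	0.8404
cg000089	0.7862	0.7229	0.7152	0.833	0.8455
cg000090	0.791	0.729	0.715	0.8376	0.8466
cg000091	0.7875	0.7196	0.7172	0.8305	0.8413
cg000092	0.7886	0.7273	0.7122	0.8309	0.2418
cg000093	0.7858	0.7254	0.411	0.8298	0.8506
cg000094	0.7892	0.5772	0.7165	0.8335	0.8445
cg000095	0.7878	0.7247	0.7123	0.8367	0.8491
cg000096	0.7815	0.7224	0.712	0.8262	0.843
cg000097	0.7829	0.7222	0.4154	0.8316	0.2425
cg000098	0.7871	0.5713	0.4144	0.8404	0.847
cg000099	0.7919	0.7275	0.7186	0.8291	0.8431
cg000100	0.7926	0.7218	0.72	0.3809	0.8389
cg000101	0.7916	0.6513	0.8051	0.8426	0.8204
cg000102	0.7884	0.6483	0.8088	0.847	0.8279
cg000103	0.7885	0.4993	0.5045	0.8474	0.2129
cg000104	0.7897	0.6484	0.8027	0.8502	0.2146
cg000105	0.7931	0.6501	0.8084	0.8427	0.214
cg000106	0.7854	0.4948	0.8021	0.8425	0.8199
cg000107	0.7876	0.6487	0.8067	0.8455	0.8241
cg000108	0.7893	0.4954	0.7986	0.8412	0.826
cg000109	0.792	0.6474	0.805	0.8496	0.8202
cg000110	0.7912	0.6477	0.809	0.3986	0.8143
cg000111	0.7884	0.649	0.8093	0.8384	0.8193
cg000112	0.7926	0.6526	0.8048	0.843	0.2164
cg000113	0.7874	0.646	0.8069	0.8414	0.818
cg000114	0.7849	0.6422	0.8033	0.8445	0.8292
cg000115	0.785	0.6438	0.8036	0.8394	0.8216
cg000116	0.7862	0.4933	0.8098	0.3936	0.2168
cg000117	0.7881	0.6418	0.8088	0.8401	0.2253
cg000118	0.7912	0.4978	0.8059	0.849	0.8241
cg000119	0.7885	0.649	0.8033	0.8452	0.818
cg000120	0.7897	0.6508	0.804	0.8425	0.8181
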