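cpg_id	CD4T	CD8T	Bcell	NK	Mono	Neu
cg000001	0.107	0.8323	0.8581	0.8415	0.8449	0.843
cg000002	0.1107	0.8552	0.8466	0.8388	0.8406	0.8467
cg000003	0.0968	0.8375	0.8546	0.8602	0.8426	0.8391
cg000004	0.0975	0.8355	0.8405	0.8319	0.8566	0.843
cg000005	0.0981	0.8446	0.8562	0.8476	0.8509	0.8599
cg000006	0.099	0.8492	0.854	0.8685	0.8382	0.8464
cg000007	0.0993	0.855	0.8471	0.8467	0.8518	0.839
cg000008	0.0953	0.8456	0.8345	0.8411	0.8401	0.843
cg000009	0.0998	0.8492	0.8493	0.8545	0.8341	0.8516
cg000010	0.1007	0.8566	0.8481	0.8588	0.8403	0.8495
cg000011	0.0974	0.8519	0.8415	0.8383	0.8506	0.8468
cg000012	0.107	0.8517	0.8544	0.8386	0.8594	0.8595
cg000013	0.107	0.871	0.8423	0.8629	0.8435	0.8483
cg000014	0.1022	0.8593	0.8487	0.8418	0.8641	0.8366
cg000015	0.1052	0.8444	0.8482	0.8528	0.8383	0.8312
cg000016	0.1016	0.8487	0.8496	0.8543	0.8597	0.8476
cg000017	0.1027	0.8456	0.8672	0.8336	0.8421	0.8506
cg000018	0.0962	0.8377	0.8617	0.8439	0.8601	0.853
cg000019	0.0886	0.8455	0.8489	0.8339	0.8537	0.8508
cg000020	0.0959	0.856	0.8433	0.8495	0.8516	0.855
cg000021	0.8532	0.0954	0.8306	0.8349	0.8571	0.8506
cg000022	0.8524	0.0953	0.8453	0.8545	0.8504	0.8417
cg000023	0.846	0.0965	0.8469	0.8574	0.8607	0.8613
cg000024	0.8472	0.1034	0.8629	0.8535	0.8544	0.8598
cg000025	0.8589	0.1032	0.8525	0.8282	0.843	0.8524
cg000026	0.8512	0.0977	0.8529	0.8442	0.8508	0.8393
cg000027	0.8487	0.0944	0.8476	0.8595	0.835	0.8563
cg000028	0.846	0.1165	0.8423	0.8458	0.8461	0.8547
cg000029	0.8294	0.0965	0.8457	0.833	0.8591	0.8518
cg000030	0.8505	0.0968	0.8464	0.8627	0.8587	0.8486
cg000031	0.8567	0.1033	0.8507	0.8573	0.8489	0.8456
cg000032	0.8551	0.091	0.8381	0.8448	0.8534	0.8443
cg000033	0.854	0.0983	0.8458	0.8465	0.8542	0.8557
cg000034	0.8524	0.1088	0.8532	0.8599	0.8539	0.8438
cg000035	0.8491	0.0908	0.8575	0.841	0.8494	0.8622
cg000036	0.8557	0.1052	0.8395	0.8533	0.8448	0.8545
cg000037	0.8464	0.1077	0.8521	0.8638	0.8413	0.8413
cg000038	0.8353	0.1105	0.8499	0.8578	0.8633	0.8435
cg000039	0.8439	0.0882	0.8439	0.8487	0.8621	0.8522
cg000040	0.8453	0.0935	0.8526	0.8537	0.8433	0.8518
cg000041	0.8439	0.8554	0.1163	0.8424	0.843	0.8602
cg000042	0.8693	0.8571	0.1032	0.8472	0.8489	0.842
cg000043	0.8549	0.8469	0.0972	0.8418	0.8404	0.8517
cg000044	0.8523	0.8361	0.0976	0.8388	0.8548	0.8633
cg000045	0.8471	0.8437	0.1007	0.8606	0.8576	0.8453
cg000046	0.856	0.8426	0.0966	0.8498	0.847	0.8552
cg000047	0.8451	0.849	0.1011	0.8612	0.8339	0.8506
cg000048	0.8372	0.8474	0.0901	0.8519	0.8397	0.842
cg000049	0.8649	0.8546	0.1028	0.8513	0.8608	0.8469
cg000050	0.8551	0.8573	0.1051	0.8381	0.8387	0.854
cg000051	0.844	0.8571	0.0948	0.8565	0.8709	0.8536
cg000052	0.8505	0.8647	0.0951	0.8408	0.8585	0.8621
cg000053	0.8404	0.8371	0.0967	0.858	0.8328	0.8439
cg000054	0.8357	0.8508	0.0901	0.8586	0.842	0.8428
cg000055	0.8399	0.8671	0.098	0.8498	0.8454	0.8496
cg000056	0.8513	0.8472	0.0959	0.8458	0.8494	0.8536
cg000057	0.863	0.847	0.1027	0.8459	0.8498	0.8425
cg000058	0.8454	0.8632	0.0912	0.8428	0.8348	0.8545
cg000059	0.8462	0.8676	0.1046	0.8487	0.8375	0.8445
cg000060	0.8466	0.8398	0.1009	0.8392	0.8336	0.8535
cg000061	0.8482	0.8418	0.8562	0.1054	0.8531	0.8525
cg000062	0.8495	0.8518	0.8495	0.0985	0.85	0.8511
cg000063	0.8403	0.8455	0.8612	0.1088	0.8464	0.8584
cg000064	0.8442	0.842	0.845	0.0967	0.8514	0.8549
cg000065	0.8462	0.8479	0.847	0.0985	0.8313	0.8396
cg000066	0.8548	0.8642	0.8374	0.1102	0.8692	0.846
cg000067	0.8463	0.8443	0.8436	0.1188	0.8443	0.8505
cg000068	0.8588	0.8456	0.8669	0.1015	0.8467	0.8478
cg000069	0.8488	0.8418	0.8611	0.1019	0.8559	0.8644
cg000070	0.8406	0.8455	0.8491	0.0944	0.8567	0.8541
cg000071	0.8625	0.8519	0.8469	0.1032	0.8535	0.8479
cg000072	0.8532	0.8615	0.8443	0.1009	0.8483	0.8499
cg000073	0.857	0.8526	0.8398	0.1035	0.8464	0.8689
cg000074	0.8524	0.8718	0.8572	0.1093	0.8402	0.8439
cg000075	0.8567	0.8465	0.8535	0.1013	0.8552	0.8452
cg000076	0.8532	0.8432	0.8575	0.0996	0.8578	0.8516
cg000077	0.8484	0.8379	0.8567	0.0983	0.8493	0.8423
cg000078	0.8563	0.8622	0.8495	0.096	0.8403	0.8409
cg000079	0.8416	0.8549	0.8372	0.0938	0.8565	0.8644
cg000080	0.8387	0.8315	0.8411	0.0999	0.8519	0.8491
cg000081	0.8459	0.8455	0.856	0.8523	0.104	0.8399
cg000082	0.8345	0.8297	0.8519	0.8425	0.0979	0.8396
cg000083	0.8559	0.8552	0.844	0.8529	0.0933	0.8586
cg000084	0.8472	0.8511	0.8482	0.8477	0.0972	0.8529
cg000085	0.8521	0.8411	0.8451	0.853	0.104	0.8332
cg000086	0.8628	0.8522	0.8591	0.8365	0.1031	0.8592
cg000087	0.8561	0.8448	0.8473	0.84	0.1105	0.8457
cg000088	0.8518	0.8653	0.8604	0.8523	0.1173	0.8522
cg000089	0.845	0.8532	0.8373	0.8515	0.111	0.8439
cg000090	0.8651	0.86	0.8314	0.8485	0.0959	0.8553
cg000091	0.8423	0.8582	0.847	0.8601	0.0991	0.827
cg000092	0.8387	0.8525	0.8563	0.852	0.0997	0.856
cg000093	0.8494	0.8472	0.8332	0.8512	0.0912	0.8644
cg000094	0.8447	0.8373	0.8659	0.8474	0.0963	0.8563
cg000095	0.8528	0.8437	0.8541	0.8354	0.1028	0.8501
cg000096	0.8405	0.8348	0.8424	0.8475	0.096	0.8443
cg000097	0.8398	0.8295	0.86	0.8389	0.0996	0.841
cg000098	0.8465	0.866	0.8488	0.84	0.0952	0.8368
cg000099	0.8495	0.8564	0.8536	0.8572	0.0961	0.8503
cg000100	0.8564	0.8421	0.86	0.8577	0.1048	0.8301
cg000101	0.8626	0.8368	0.8507	0.844	0.8539	0.1045
cg000102	0.8476	0.8471	0.8487	0.8467	0.8539	0.0998
cg000103	0.8462	0.8472	0.8522	0.8422	0.851	0.1102
cg000104	0.8587	0.848	0.8382	0.8494	0.8513	0.0996
cg000105	0.8578	0.8411	0.8621	0.848	0.8493	0.0973
cg000106	0.8473	0.8441	0.8461	0.8424	0.8361	0.1045
cg000107	0.8462	0.8463	0.8434	0.8497	0.8546	0.1042
cg000108	0.8615	0.8616	0.8417	0.8361	0.8406	0.0914
cg000109	0.8556	0.8502	0.8599	0.8405	0.848	0.1002
cg000110	0.858	0.8594	0.8448	0.8407	0.8513	0.1031
cg000111	0.8376	0.8441	0.8557	0.8498	0.8653	0.1044
cg000112	0.856	0.8404	0.8468	0.8583	0.8597	0.1057
cg000113	0.8467	0.8503	0.8507	0.8393	0.8556	0.0957
cg000114	0.8575	0.8321	0.8363	0.8409	0.8508	0.0975
cg000115	0.8451	0.8444	0.8483	0.8437	0.834	0.1005
cg000116	0.8347	0.8535	0.8605	0.8415	0.8504	0.0921
cg000117	0.8497	0.8552	0.8558	0.8378	0.8373	0.092
cg000118	0.8493	0.8492	0.851	0.8534	0.8543	0.103
cg000119	0.844	0.8425	0.8485	0.85	0.8634	0.106
cg000120	0.8437	0.8544	0.8414	0.855	0.86240000000000006	0.1111
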