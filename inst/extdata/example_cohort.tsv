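ID	ctrl_01	ctrl_02	ctrl_03	ctrl_04	ctrl_05	pat_01	pat_02	pat_03	pat_04	pat_05
hsa-miR-425	1.4824	-1.3326	-0.8599	2.8139	1.2079	2.7398	2.9796	2.0102	3.7308	2.2315
hsa-miR-15b	-0.295	-1.9691	0.6415	-0.4965	-1.4054	1.4498	-0.6165	1.3005	0.4103	1.6157
hsa-miR-185	-0.7489	-1.4746	0.4236	0.9885	0.1923	3.3235	2.8075	1.8315	1.3923	1.7474
hsa-miR-92a	-0.3857	-0.3186	-0.8315	-0.1194	0.6859	2.6105	3.7389	-0.0201	2.4667	1.8189
hsa-miR-140-3p	0.1127	-1.9947	-0.2848	1.4062	0.5852	2.1051	1.6416	0.9653	2.093	2.87
hsa-miR-320a	-3.0548	-3.9204	-3.8649	-1.7474	-1.8006	0.8028	-1.5592	2.0664	-0.4653	-1.4281
hsa-miR-486-5p	-0.5785	-3.1444	0.5805	-2.0926	2.6652	0.7336	2.3082	1.6375	1.9712	0.7606
hsa-miR-16	-1.2846	-3.1539	-2.3689	0.6678	0.3305	0.5375	0.9726	1.2063	1.7719	2.2036
hsa-miR-191	0.4366	-0.9254	-1.6365	-0.8488	0.6728	2.2814	2.8597	2.8083	2.7751	1.4937
hsa-miR-106b	-0.3011	-2.6457	-0.7223	-1.319	0.7294	2.0413	1.474	3.9946	1.2495	0.6951
hsa-miR-19b	0.9716	-0.0696	-0.6161	-1.5139	-0.4709	1.3458	3.0894	1.2041	2.3364	2.1776
hsa-miR-30d	0.0783	-0.083	-1.7986	-1.5577	-1.7863	-1.2471	3.5998	2.534	-0.993	2.2109
hsa-miR-sim-0013	-0.898	0.0599	-2.0388	-0.2032	0.3194	-2.7468	1.3209	-0.3516	0.3984	-0.5455
hsa-miR-sim-0014	0.5666	-0.0369	-0.1071	0.6732	0.761	-1.1029	1.0337	-0.0697	0.1836	-0.0359
hsa-miR-sim-0015	-3.1566	-3.8012	-1.1895	-2.8917	-2.1265	-4.6002	-2.3373	-2.4184	-0.4895	-2.3423
hsa-miR-sim-0016	0.4809	1.1022	0.8153	0.49	1.9739	1.1502	3.1042	2.3709	2.6353	-1.3923
hsa-miR-sim-0017	1.6856	-1.1556	3.5168	-0.323	1.0289	1.24	1.3789	1.468	1.7519	-1.1391
hsa-miR-sim-0018	-0.6955	1.3982	1.1695	0.7305	1.3208	-0.3787	3.5748	1.5367	2.4384	0.1347
hsa-miR-sim-0019	-0.2068	-1.7802	1.6033	0.826	-1.8328	-1.5108	0.7149	0.5038	0.9536	-1.6935
hsa-miR-sim-0020	0.1472	0.8658	0.2922	-1.0371	2.1033	0.4511	1.0685	3.0943	1.7103	-1.8148
hsa-miR-sim-0021	2.7783	-6.2574	1.7398	-2.7608	0.0796	0.6821	0.1005	8.6398	-3.4273	7.6449
hsa-miR-sim-0022	-1.1417	6.289	-3.4526	6.3055	-1.1471	-2.2542	0.5872	-11.5979	3.0512	-8.0337
hsa-miR-sim-0023	-3.4833	6.4032	-4.2114	3.1778	-1.9336	-1.9191	-1.7666	-10.8314	0.6153	-9.1773
hsa-miR-sim-0024	0.5764	7.067	-1.9406	6.7011	0.3856	-0.4181	1.6328	-8.2081	5.7793	-5.2835
hsa-miR-sim-0025	-1.2141	6.9398	-1.9115	2.6478	-2.8291	-1.2863	1.3017	-9.1458	2.5858	-6.9675
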