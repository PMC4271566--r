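chain	resnum	code	x	y	z
A	1	H	1.983	1.845	7.747
A	2	H	3.892	3.911	7.634
A	3	H	7.116	6.381	7.831
A	4	H	9.689	7.899	6.794
A	5	C	12.515	9.287	5.69
A	6	C	14.705	10.707	5.092
A	7	C	17.242	11.145	4.971
A	8	C	19.672	10.3	2.683
A	9	E	21.81	10.667	2.514
A	10	E	23.283	9.891	0.814
A	11	E	26.56	8.867	0.68
A	12	E	29.007	8.033	-1.145
A	13	C	31.423	5.395	-2.089
A	14	C	33.412	3.794	-2.783
A	15	C	36.36	1.068	-4.908
A	16	C	38.16	-1.087	-5.376
A	17	H	40.389	-2.231	-5.694
A	18	H	43.023	-5.316	-6.344
A	19	H	45.335	-7.392	-6.763
A	20	H	47.957	-8.952	-7.728
A	21	T	50.103	-8.517	-8.615
A	22	T	53.75	-11.207	-7.721
A	23	T	55.343	-11.052	-7.632
A	24	T	57.73	-11.237	-7.274
A	25	E	59.873	-10.946	-6.554
A	26	E	63.376	-9.479	-6.911
A	27	E	65.087	-8.758	-5.347
A	28	E	67.293	-6.536	-6.614
A	29	C	69.103	-4.352	-4.409
A	30	C	71.355	-2.652	-3.087
A	31	C	74.436	-1.408	-2.541
A	32	C	76.396	0.579	-1.391
A	33	H	78.719	2.772	-0.183
A	34	H	81.621	5.423	1.622
A	35	H	83.646	7.511	3.233
A	36	H	86.89	10.19	3.939
A	37	C	88.083	10.582	4.283
A	38	C	90.948	10.318	5.395
A	39	C	93.535	11.102	7.03
A	40	C	95.83	12.233	7.152
A	41	E	98.785	10.704	7.561
A	42	E	99.922	9.45	7.494
A	43	E	102.673	7.722	8.17
A	44	E	106.239	6.482	8.31
A	45	T	107.595	4.384	7.701
A	46	T	109.64	2.905	7.195
A	47	T	112.918	-0.578	7.603
A	48	T	115.445	-1.287	6.519
A	49	H	117.651	-3.644	6.01
A	50	H	119.607	-5.57	5.48
A	51	H	121.893	-7.268	3.356
A	52	H	124.99	-9.355	3.123
A	53	C	127.36	-9.951	2.365
A	54	C	130.198	-11.752	1.402
A	55	C	131.736	-11.436	-0.381
A	56	C	134.876	-10.874	-1.643
A	57	E	137.203	-9.675	-1.845
A	58	E	138.984	-9.581	-3.713
A	59	E	140.873	-7.92	-4.692
A	60	E	143.378	-5.931	-4.517
A	61	C	146.42	-3.57	-6.095
A	62	C	149.348	-1.547	-6.3
A	63	C	151.058	0.111	-7.843
A	64	C	154.017	2.242	-6.881
A	65	H	155.995	5.021	-8.025
A	66	H	158.53	6.273	-7.986
A	67	H	161.113	8.095	-8.227
A	68	H	163.49	8.698	-9.087
A	69	C	165.741	10.112	-7.19
A	70	C	167.898	11.43	-7.106
A	71	C	170.109	11.725	-6.427
A	72	C	172.476	10.986	-4.884
A	73	E	175.786	9.977	-4.035
A	74	E	178.226	8.923	-3.572
A	75	E	180.121	6.628	-2.401
A	76	E	181.43	5.626	-1.192
A	77	C	185.216	3.277	-0.265
A	78	C	187.197	0.579	0.875
A	79	C	189.642	-0.28	2.339
A	80	C	191.84	-3.033	2.625
A	81	H	194.776	-5.041	4.055
A	82	H	196.141	-6.813	5.397
A	83	H	199.719	-8.299	5.868
A	84	H	201.402	-10.279	6.5
A	85	T	204.297	-10.518	7.218
A	86	T	206.018	-10.992	7.496
A	87	T	208.638	-11.645	7.824
A	88	T	210.971	-10.045	7.748
A	89	E	213.427	-9.568	7.451
A	90	E	216.483	-7.569	7.65
A	91	E	219.179	-6.972	7.646
A	92	E	221.489	-4.804	6.686
A	93	C	222.997	-2.657	5.863
A	94	C	226.575	-0.228	4.765
A	95	C	228.16	1.72	4.3
A	96	C	230.718	4.137	3.063
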