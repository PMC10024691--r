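channel_id	length_mm	flow_ul_min
ch01	117.7	7.699
ch01	117.7	7.641
ch01	117.7	7.619
ch01	117.7	7.588
ch02	119	7.294
ch02	119	7.516
ch02	119	7.641
ch02	119	7.622
ch03	120.29	7.593
ch03	120.29	7.616
ch03	120.29	7.719
ch03	120.29	7.601
ch04	121.59	7.617
ch04	121.59	7.57
ch04	121.59	7.564
ch04	121.59	7.642
ch05	122.89	7.606
ch05	122.89	7.495
ch05	122.89	7.515
ch05	122.89	7.539
ch06	124.19	7.557
ch06	124.19	7.462
ch06	124.19	7.542
ch06	124.19	7.548
ch07	125.48	7.54
ch07	125.48	7.619
ch07	125.48	7.514
ch07	125.48	7.313
ch08	126.78	7.439
ch08	126.78	7.239
ch08	126.78	7.4
ch08	126.78	7.524
ch09	128.08	7.42
ch09	128.08	7.473
ch09	128.08	7.409
ch09	128.08	7.499
ch10	129.38	7.23
ch10	129.38	7.43
ch10	129.38	7.38
ch10	129.38	7.525
ch11	130.67	7.198
ch11	130.67	7.279
ch11	130.67	7.494
ch11	130.67	7.338
ch12	131.97	7.274
ch12	131.97	7.391
ch12	131.97	7.243
ch12	131.97	7.212
ch13	133.27	7.426
ch13	133.27	7.439
ch13	133.27	7.401
ch13	133.27	7.42
ch14	134.56	7.333
ch14	134.56	7.135
ch14	134.56	7.477
ch14	134.56	7.199
ch15	135.86	7.283
ch15	135.86	7.422
ch15	135.86	7.239
ch15	135.86	7.207
ch16	137.16	7.269
ch16	137.16	7.051
ch16	137.16	7.107
ch16	137.16	7.317
ch17	138.46	7.334
ch17	138.46	7.263
ch17	138.46	7.114
ch17	138.46	7.264
ch18	139.75	7.347
ch18	139.75	7.127
ch18	139.75	7.23
ch18	139.75	7.049
ch19	141.05	7.172
ch19	141.05	7.223
ch19	141.05	7.154
ch19	141.05	6.973
ch20	142.35	6.935
ch20	142.35	7.052
ch20	142.35	7.31
ch20	142.35	7.204
ch21	143.65	7.195
ch21	143.65	7.201
ch21	143.65	7.163
ch21	143.65	7.236
ch22	144.94	7.166
ch22	144.94	7.111
ch22	144.94	6.989
ch22	144.94	7.104
ch23	146.24	6.952
ch23	146.24	7.178
ch23	146.24	7.113
ch23	146.24	7.26
ch24	147.54	6.887
ch24	147.54	7.087
ch24	147.54	7.012
ch24	147.54	7.146
ch25	148.84	6.959
ch25	148.84	6.878
ch25	148.84	7.055
ch25	148.84	6.963
ch26	150.13	6.861
ch26	150.13	6.837
ch26	150.13	7.036
ch26	150.13	7.04
ch27	151.43	6.999
ch27	151.43	7.039
ch27	151.43	6.98
ch27	151.43	6.765
ch28	152.73	6.984
ch28	152.73	6.984
ch28	152.73	6.938
ch28	152.73	7.057
ch29	154.02	6.918
ch29	154.02	6.928
ch29	154.02	6.712
ch29	154.02	6.872
ch30	155.32	6.969
ch30	155.32	6.865
ch30	155.32	6.889
ch30	155.32	6.917
ch31	156.62	6.858
ch31	156.62	6.872
ch31	156.62	6.854
ch31	156.62	6.909
ch32	157.92	6.949
ch32	157.92	6.927
ch32	157.92	6.834
ch32	157.92	6.992
ch33	159.21	6.837
ch33	159.21	7.017
ch33	159.21	6.822
ch33	159.21	6.884
ch34	160.51	6.712
ch34	160.51	6.754
ch34	160.51	6.838
ch34	160.51	6.774
ch35	161.81	6.53
ch35	161.81	6.998
ch35	161.81	6.795
ch35	161.81	6.793
ch36	163.11	6.638
ch36	163.11	6.819
ch36	163.11	6.812
ch36	163.11	6.722
ch37	164.4	6.667
ch37	164.4	6.721
ch37	164.4	6.574
ch37	164.4	6.718
ch38	165.7	6.789
ch38	165.7	6.662
ch38	165.7	6.504
ch38	165.7	6.701
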