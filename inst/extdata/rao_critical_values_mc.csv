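"n","alpha","u_crit"
4,0.1,168.007
4,0.05,186.434
4,0.01,221.233
4,0.001,247.396
5,0.1,168.658
5,0.05,183.446
5,0.01,211.92
5,0.001,245.42
6,0.1,166.173
6,0.05,180.429
6,0.01,206.57
6,0.001,236.551
7,0.1,164.985
7,0.05,177.79
7,0.01,202.479
7,0.001,229.275
8,0.1,163.524
8,0.05,175.687
8,0.01,198.581
8,0.001,224.113
9,0.1,162.35
9,0.05,173.696
9,0.01,195.254
9,0.001,219.407
10,0.1,161.253
10,0.05,171.999
10,0.01,192.391
10,0.001,215.68
11,0.1,160.288
11,0.05,170.495
11,0.01,190.037
11,0.001,211.945
12,0.1,159.361
12,0.05,169.146
12,0.01,187.633
12,0.001,208.666
13,0.1,158.515
13,0.05,167.928
13,0.01,185.618
13,0.001,205.807
14,0.1,157.775
14,0.05,166.756
14,0.01,183.897
14,0.001,203.212
15,0.1,157.056
15,0.05,165.706
15,0.01,182.337
15,0.001,201.097
16,0.1,156.39
16,0.05,164.822
16,0.01,180.724
16,0.001,198.837
17,0.1,155.857
17,0.05,163.977
17,0.01,179.462
17,0.001,196.818
18,0.1,155.277
18,0.05,163.192
18,0.01,178.152
18,0.001,195.422
19,0.1,154.784
19,0.05,162.453
19,0.01,176.982
19,0.001,193.549
20,0.1,154.328
20,0.05,161.789
20,0.01,175.999
20,0.001,192.252
21,0.1,153.835
21,0.05,161.146
21,0.01,175.027
21,0.001,190.696
22,0.1,153.432
22,0.05,160.535
22,0.01,174.201
22,0.001,189.704
23,0.1,153.117
23,0.05,160.064
23,0.01,173.31
23,0.001,188.52
24,0.1,152.69
24,0.05,159.506
24,0.01,172.421
24,0.001,187.075
25,0.1,152.301
25,0.05,158.927
25,0.01,171.645
25,0.001,185.964
26,0.1,152.012
26,0.05,158.537
26,0.01,170.868
26,0.001,184.91
27,0.1,151.658
27,0.05,158.068
27,0.01,170.281
27,0.001,184.116
28,0.1,151.354
28,0.05,157.635
28,0.01,169.554
28,0.001,183.211
29,0.1,151.094
29,0.05,157.271
29,0.01,168.974
29,0.001,182.408
30,0.1,150.777
30,0.05,156.858
30,0.01,168.417
30,0.001,181.475
31,0.1,150.503
31,0.05,156.49
31,0.01,167.852
31,0.001,180.757
32,0.1,150.293
32,0.05,156.153
32,0.01,167.178
32,0.001,179.756
33,0.1,150.052
33,0.05,155.816
33,0.01,166.755
33,0.001,179.009
34,0.1,149.799
34,0.05,155.52
34,0.01,166.258
34,0.001,178.585
35,0.1,149.596
35,0.05,155.206
35,0.01,165.882
35,0.001,177.913
36,0.1,149.379
36,0.05,154.891
36,0.01,165.401
36,0.001,177.264
37,0.1,149.172
37,0.05,154.644
37,0.01,164.908
37,0.001,176.621
38,0.1,148.956
38,0.05,154.303
38,0.01,164.503
38,0.001,176.056
39,0.1,148.764
39,0.05,154.089
39,0.01,164.102
39,0.001,175.464
40,0.1,148.603
40,0.05,153.824
40,0.01,163.769
40,0.001,174.949
41,0.1,148.419
41,0.05,153.586
41,0.01,163.382
41,0.001,174.495
42,0.1,148.262
42,0.05,153.341
42,0.01,162.987
42,0.001,174.021
43,0.1,148.1
43,0.05,153.119
43,0.01,162.662
43,0.001,173.409
44,0.1,147.927
44,0.05,152.905
44,0.01,162.334
44,0.001,172.844
45,0.1,147.745
45,0.05,152.659
45,0.01,162.053
45,0.001,172.582
46,0.1,147.616
46,0.05,152.477
46,0.01,161.69
46,0.001,172.19
47,0.1,147.467
47,0.05,152.256
47,0.01,161.406
47,0.001,171.921
48,0.1,147.322
48,0.05,152.086
48,0.01,161.096
48,0.001,171.394
49,0.1,147.195
49,0.05,151.89
49,0.01,160.746
49,0.001,170.895
50,0.1,147.047
50,0.05,151.71
50,0.01,160.471
50,0.001,170.522
51,0.1,146.92
51,0.05,151.567
51,0.01,160.259
51,0.001,170.197
52,0.1,146.795
52,0.05,151.379
52,0.01,160.025
52,0.001,169.845
53,0.1,146.658
53,0.05,151.163
53,0.01,159.736
53,0.001,169.354
54,0.1,146.536
54,0.05,150.991
54,0.01,159.498
54,0.001,169.109
55,0.1,146.424
55,0.05,150.857
55,0.01,159.282
55,0.001,168.862
56,0.1,146.3
56,0.05,150.67
56,0.01,158.982
56,0.001,168.507
57,0.1,146.218
57,0.05,150.565
57,0.01,158.783
57,0.001,168.133
58,0.1,146.093
58,0.05,150.407
58,0.01,158.575
58,0.001,167.919
59,0.1,145.988
59,0.05,150.245
59,0.01,158.308
59,0.001,167.522
60,0.1,145.872
60,0.05,150.114
60,0.01,158.157
60,0.001,167.374
61,0.1,145.788
61,0.05,150.013
61,0.01,157.99
61,0.001,167.022
62,0.1,145.68
62,0.05,149.842
62,0.01,157.711
62,0.001,166.61
63,0.1,145.577
63,0.05,149.705
63,0.01,157.484
63,0.001,166.506
64,0.1,145.482
64,0.05,149.588
64,0.01,157.356
64,0.001,166.098
65,0.1,145.379
65,0.05,149.45
65,0.01,157.182
65,0.001,165.996
66,0.1,145.297
66,0.05,149.339
66,0.01,156.993
66,0.001,165.762
67,0.1,145.202
67,0.05,149.219
67,0.01,156.836
67,0.001,165.472
68,0.1,145.107
68,0.05,149.102
68,0.01,156.644
68,0.001,165.203
69,0.1,145.044
69,0.05,148.989
69,0.01,156.493
69,0.001,164.925
70,0.1,144.948
70,0.05,148.865
70,0.01,156.265
70,0.001,164.753
71,0.1,144.883
71,0.05,148.781
71,0.01,156.131
71,0.001,164.527
72,0.1,144.791
72,0.05,148.65
72,0.01,155.915
72,0.001,164.302
73,0.1,144.699
73,0.05,148.537
73,0.01,155.824
73,0.001,164.029
74,0.1,144.629
74,0.05,148.427
74,0.01,155.59
74,0.001,163.705
75,0.1,144.556
75,0.05,148.362
75,0.01,155.492
75,0.001,163.676
76,0.1,144.485
76,0.05,148.256
76,0.01,155.36
76,0.001,163.476
77,0.1,144.409
77,0.05,148.139
77,0.01,155.206
77,0.001,163.186
78,0.1,144.343
78,0.05,148.054
78,0.01,155.069
78,0.001,163.028
79,0.1,144.262
79,0.05,147.932
79,0.01,154.917
79,0.001,162.791
80,0.1,144.212
80,0.05,147.862
80,0.01,154.814
80,0.001,162.571
81,0.1,144.138
81,0.05,147.784
81,0.01,154.63
81,0.001,162.405
82,0.1,144.059
82,0.05,147.674
82,0.01,154.501
82,0.001,162.151
83,0.1,143.999
83,0.05,147.564
83,0.01,154.35
83,0.001,162.014
84,0.1,143.937
84,0.05,147.506
84,0.01,154.293
84,0.001,161.952
85,0.1,143.878
85,0.05,147.404
85,0.01,154.116
85,0.001,161.649
86,0.1,143.809
86,0.05,147.336
86,0.01,154.008
86,0.001,161.556
87,0.1,143.759
87,0.05,147.272
87,0.01,153.882
87,0.001,161.36
88,0.1,143.682
88,0.05,147.183
88,0.01,153.757
88,0.001,161.125
89,0.1,143.625
89,0.05,147.085
89,0.01,153.665
89,0.001,160.984
90,0.1,143.57
90,0.05,147.039
90,0.01,153.534
90,0.001,160.853
91,0.1,143.519
91,0.05,146.927
91,0.01,153.389
91,0.001,160.755
92,0.1,143.438
92,0.05,146.834
92,0.01,153.263
92,0.001,160.61
93,0.1,143.403
93,0.05,146.788
93,0.01,153.207
93,0.001,160.491
94,0.1,143.337
94,0.05,146.731
94,0.01,153.066
94,0.001,160.259
95,0.1,143.297
95,0.05,146.651
95,0.01,152.982
95,0.001,160.155
96,0.1,143.232
96,0.05,146.569
96,0.01,152.883
96,0.001,160.019
97,0.1,143.181
97,0.05,146.476
97,0.01,152.755
97,0.001,159.838
98,0.1,143.124
98,0.05,146.44
98,0.01,152.678
98,0.001,159.824
99,0.1,143.071
99,0.05,146.349
99,0.01,152.603
99,0.001,159.647
100,0.1,143.022
100,0.05,146.285
100,0.01,152.478
100,0.001,159.48
150,0.1,141.173
150,0.05,143.833
150,0.01,148.871
150,0.001,154.589
200,0.1,140.063
200,0.05,142.354
200,0.01,146.658
200,0.001,151.553
300,0.1,138.7
300,0.05,140.556
300,0.01,144.073
300,0.001,148.015
500,0.1,137.335
500,0.05,138.773
500,0.01,141.469
500,0.001,144.575
1000,0.1,135.924
1000,0.05,136.938
1000,0.01,138.843
1000,0.001,140.98
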