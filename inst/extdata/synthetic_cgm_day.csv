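timestamp,glucose_mmol_per_L
0,11.202
300,11.328
600,11.457
900,11.446
1200,11.097
1500,10.814
1800,10.326
2100,10.083
2400,10.007
2700,9.971
3000,9.857
3300,9.763
3600,9.916
3900,9.821
4200,9.941
4500,9.981
4800,9.857
5100,9.61
5400,9.358
5700,9.238
6000,9.487
6300,9.686
6600,9.677
6900,9.844
7200,9.906
7500,9.597
7800,9.535
8100,9.376
8400,9.393
8700,9.058
9000,8.783
9300,8.605
9600,8.616
9900,8.51
10200,8.278
10500,8.389
10800,8.332
11100,8.479
11400,8.046
11700,7.97
12000,7.882
12300,7.628
12600,7.74
12900,7.915
13200,7.98
13500,8.102
13800,7.951
14100,8.067
14400,8.103
14700,8.161
15000,8.097
15300,7.964
15600,7.83
15900,7.858
16200,7.628
16500,7.312
16800,7.122
17100,7.129
17400,6.823
17700,6.658
18000,6.623
18300,6.571
18600,6.46
18900,6.421
19200,6.62
19500,6.546
19800,6.945
20100,6.982
20400,7.14
20700,7.143
21000,7.325
21300,7.443
21600,7.449
21900,7.645
22200,7.935
22500,8.231
22800,8.522
23100,8.496
23400,8.443
23700,8.516
24000,8.397
24300,8.343
24600,8.218
24900,8.48
25200,8.388
25500,8.418
25800,8.541
26100,9.009
26400,9.677
26700,10.261
27000,10.749
27300,11.276
27600,11.337
27900,11.44
28200,11.559
28500,11.494
28800,11.235
29100,10.92
29400,10.472
29700,10.093
30000,9.972
30300,9.591
30600,9.215
30900,8.884
31200,8.438
31500,8.358
31800,8.11
32100,7.925
32400,7.809
32700,7.527
33000,7.169
33300,6.926
33600,6.702
33900,6.4
34200,6.216
34500,6.154
34800,5.756
35100,5.545
35400,5.424
35700,5.328
36000,5.274
36300,5.259
36600,5.372
36900,5.214
37200,5.131
37500,5.156
37800,4.977
38100,4.829
38400,4.876
38700,5.05
39000,5.222
39300,5.081
39600,4.785
39900,4.784
40200,4.869
40500,4.706
40800,4.846
41100,5.136
41400,5.18
41700,5.19
42000,5.436
42300,5.571
42600,5.886
42900,5.925
43200,6.153
43500,6.467
43800,6.514
44100,6.378
44400,6.284
44700,6.22
45000,6.1
45300,5.866
45600,6.009
45900,6.49
46200,7.036
46500,7.809
46800,8.611
47100,9.355
47400,9.831
47700,9.689
48000,9.455
48300,9.022
48600,8.785
48900,8.175
49200,7.731
49500,7.422
49800,7.388
50100,7.268
50400,7.249
50700,7.267
51000,7.101
51300,6.883
51600,6.828
51900,6.945
52200,7.202
52500,7.173
52800,6.979
53100,6.878
53400,6.457
53700,6.252
54000,6.08
54300,5.937
54600,5.729
54900,5.813
55200,5.778
55500,5.693
55800,5.835
56100,5.969
56400,5.984
56700,5.793
57000,5.761
57300,5.817
57600,5.719
57900,5.471
58200,5.404
58500,5.451
58800,5.529
59100,5.617
59400,5.688
59700,5.792
60000,5.924
60300,5.946
60600,5.967
60900,6.055
61200,6.175
61500,6.23
61800,6.186
62100,5.998
62400,5.989
62700,6.091
63000,6.01
63300,5.908
63600,5.634
63900,5.712
64200,5.901
64500,5.993
64800,6.155
65100,6.246
65400,6.461
65700,6.449
66000,6.631
66300,6.536
66600,6.666
66900,6.629
67200,6.546
67500,6.323
67800,6.124
68100,6.148
68400,6.316
68700,6.289
69000,6.277
69300,6.448
69600,7.031
69900,8.01
70200,8.675
70500,9.089
70800,9.116
71100,9.414
71400,9.5
71700,9.162
72000,8.97
72300,8.686
72600,8.434
72900,8.38
73200,8.213
73500,8.081
73800,7.923
74100,7.931
74400,7.917
74700,8.155
75000,7.918
75300,7.999
75600,8.03
75900,8.121
76200,8.119
76500,8.057
76800,8.004
77100,8.131
77400,8.716
77700,9.017
78000,9.191
78300,9.328
78600,9.604
78900,9.643
79200,9.774
79500,9.889
79800,9.747
80100,9.773
80400,9.85
80700,9.976
81000,10.222
81300,10.446
81600,10.56
81900,10.547
82200,10.726
82500,11.014
82800,11.39
83100,11.662
83400,11.456
83700,11.541
84000,11.226
84300,11.193
84600,11.205
84900,11.433
85200,11.641
85500,11.959
85800,12.273
86100,12.359
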