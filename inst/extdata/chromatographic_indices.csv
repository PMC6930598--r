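compound,C8_RM0,C8_m,C8_C0,C8_mRM,C8_PC1,C18_RM0,C18_m,C18_C0,C18_mRM,C18_PC1,HPLC_logkw,MEKC_logk
1,1.496,2.198,0.681,0.068,3.593,2.771,3.153,0.879,-0.266,3.952,2.360,0.135
2,3.120,3.730,0.836,0.696,-2.265,3.702,4.031,0.918,0.477,-2.999,3.980,-0.058
3,2.162,2.805,0.771,0.339,1.033,2.045,2.414,0.847,0.114,0.130,2.870,-0.106
4,1.893,2.593,0.730,0.208,2.319,1.935,2.440,0.793,-0.017,1.508,2.790,0.141
5,2.929,3.592,0.815,0.594,-1.271,3.143,3.561,0.882,0.294,-1.278,3.760,-0.159
6,3.293,4.063,0.810,0.652,-1.648,3.012,3.363,0.896,0.322,-1.656,3.680,-0.050
7,1.791,2.477,0.723,0.182,2.530,1.616,2.087,0.774,-0.054,1.742,2.530,0.066
8,2.175,2.772,0.785,0.374,0.641,2.098,2.465,0.851,0.126,0.022,2.900,0.074
9,2.834,3.539,0.801,0.533,-0.648,2.901,3.345,0.867,0.225,-0.648,2.770,0.058
10,1.919,2.558,0.750,0.257,1.779,1.775,2.186,0.812,0.026,0.952,2.580,0.040
11,3.477,4.192,0.829,0.752,-2.635,3.041,3.324,0.915,0.382,-2.284,3.830,0.094
12,2.238,2.094,1.068,0.876,-5.068,3.017,3.633,0.830,0.111,0.563,3.140,0.064
13,2.988,3.555,0.840,0.677,-2.168,3.175,3.457,0.918,0.409,-2.514,3.690,-0.003
14,0.991,1.831,0.541,-0.199,6.251,0.945,1.841,0.513,-0.528,6.519,2.070,0.065
15,2.722,3.391,0.803,0.518,-0.571,2.770,3.111,0.890,0.281,-1.322,3.280,0.104
16,1.951,2.734,0.714,0.174,2.758,1.948,2.641,0.737,-0.165,3.120,2.810,0.084
17,2.864,3.579,0.800,0.538,-0.681,3.158,3.649,0.865,0.238,-0.656,3.700,-0.112
18,2.808,3.476,0.808,0.548,-0.832,3.151,3.743,0.842,0.157,0.226,3.670,0.022
19,2.421,3.023,0.801,0.456,-0.103,2.509,2.888,0.869,0.198,-0.561,3.140,-0.388
20,2.123,2.780,0.764,0.317,1.259,2.314,2.778,0.833,0.092,0.493,2.970,0.076
21,2.568,3.182,0.807,0.500,-0.491,2.412,2.718,0.887,0.238,-1.021,3.330,0.065
22,2.907,3.498,0.831,0.634,-1.748,3.028,3.319,0.912,0.373,-2.206,3.500,0.115
23,2.123,2.664,0.797,0.391,0.403,2.066,2.569,0.804,0.011,1.248,2.950,-0.176
24,2.431,3.033,0.801,0.459,-0.127,2.731,3.107,0.879,0.245,-0.966,3.210,0.028
25,2.557,3.026,0.845,0.591,-1.536,2.664,2.980,0.894,0.280,-1.377,3.230,-0.161
26,2.461,2.990,0.823,0.518,-0.773,2.771,3.153,0.879,0.249,-0.987,3.240,0.064
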