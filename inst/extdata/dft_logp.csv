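compound,B3LYP_631Gp,B3LYP_6311Gppdp,CAMB3LYP_6311Gppdp,wB97XD_6311Gppdp,PBE0_6311Gppdp,PBE0_6311Gpp2df2dp
1,-1.47,-0.79,-0.78,-0.74,-0.70,-0.54
2,1.48,1.82,1.68,1.81,1.93,2.06
3,0.02,0.36,0.30,0.30,0.45,0.59
4,-0.43,0.24,0.00,0.35,-0.50,0.68
5,0.71,1.48,1.58,1.80,1.55,1.58
6,1.69,1.85,2.16,1.77,1.93,2.08
7,0.22,1.35,1.65,1.54,1.11,-0.06
8,0.57,0.85,0.77,0.79,0.94,1.10
9,0.80,1.40,1.21,1.26,1.57,1.62
10,-0.09,-0.24,-0.31,-0.28,-0.16,-0.01
11,-0.70,0.90,0.70,0.85,0.05,0.25
12,-2.58,-1.70,-1.81,-1.76,-1.57,-1.26
13,1.55,2.00,2.05,1.88,1.99,2.08
14,-1.94,-1.29,-1.31,-1.26,-1.23,-1.10
15,0.64,1.47,1.36,1.42,1.54,1.68
16,-0.18,0.15,0.01,0.07,0.22,0.38
17,0.64,1.37,1.33,1.47,1.43,1.58
18,-1.29,0.01,0.57,0.55,0.48,1.14
19,-0.76,-0.07,-0.11,-0.10,0.07,0.30
20,0.01,0.39,0.32,0.30,0.52,0.67
21,0.50,0.77,0.76,0.78,0.89,1.04
22,0.71,1.03,0.98,0.93,1.11,1.25
23,-1.86,-1.86,-0.68,-0.62,-0.56,-0.32
24,0.43,0.65,0.63,0.63,0.79,0.96
25,-1.16,-0.32,-0.30,-0.29,-0.13,0.28
26,0.34,0.70,0.64,0.64,0.79,0.94
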