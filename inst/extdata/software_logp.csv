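compound,logP_ChemDraw,ClogP_ChemDraw,VlogP,logPC_Spartan,logPV_Spartan,miLogP,logP_KOWWIN,AlogPs,AClogP,AlogP,MlogP,XlogP2,XlogP3
1,2.36,1.00,2.13,1.94,0.03,1.50,1.69,1.26,3.45,2.02,2.07,2.33,2.33
2,2.82,3.83,2.96,4.47,2.41,3.16,3.94,3.67,3.37,3.95,3.70,3.44,3.96
3,2.27,2.06,2.31,2.73,0.46,1.57,2.23,2.08,2.01,2.37,2.37,1.73,2.47
4,0.32,1.76,1.03,1.59,0.82,1.82,0.28,1.33,2.04,1.53,2.18,1.72,1.70
5,1.61,4.10,2.02,3.49,1.43,3.04,1.88,2.71,3.52,3.20,3.51,3.44,3.36
6,2.09,3.44,2.99,3.73,1.64,2.76,3.70,3.20,2.72,3.38,3.36,2.84,3.39
7,-0.42,1.37,0.95,0.86,-0.71,1.42,0.03,0.72,1.39,0.96,1.77,1.12,1.13
8,1.07,2.20,2.01,2.34,0.15,1.54,2.48,2.14,1.78,2.15,2.24,1.55,2.26
9,0.87,3.72,1.93,2.76,0.81,2.63,1.64,2.11,2.86,2.63,3.17,2.84,2.79
10,1.53,1.67,2.32,2.00,-0.20,1.16,1.99,1.55,1.35,1.80,1.94,1.13,1.89
11,2.35,3.45,3.33,3.48,1.12,2.80,3.86,3.25,2.51,3.35,2.83,2.67,3.33
12,1.19,0.11,1.87,0.69,4.72,0.54,-0.04,1.17,2.78,1.38,1.02,0.72,0.92
13,1.98,3.26,3.08,3.24,0.81,2.60,3.46,3.11,2.71,3.13,2.82,2.48,3.14
14,1.62,0.61,2.27,1.21,-0.60,1.09,1.44,1.27,2.79,1.45,1.62,1.72,1.76
15,1.52,2.73,2.59,2.82,0.52,2.04,2.97,2.58,2.25,2.67,2.53,1.91,2.79
16,0.91,1.77,1.83,2.22,0.64,1.32,2.20,1.59,1.24,2.99,2.45,1.40,2.01
17,1.01,3.86,2.26,2.91,0.87,2.80,1.84,2.43,2.92,2.83,3.56,3.00,2.89
18,2.48,2.74,3.43,3.35,0.72,2.39,3.21,3.22,3.40,3.34,2.57,2.18,3.30
19,2.40,2.35,2.55,2.61,0.21,1.60,2.31,2.08,1.90,2.35,2.13,1.65,2.44
20,2.41,2.27,2.60,2.89,0.66,0.73,2.43,2.41,2.06,2.57,2.78,1.89,2.57
21,2.89,2.84,3.01,3.29,1.36,2.22,2.88,2.62,2.62,3.03,2.91,2.35,3.10
22,3.10,3.01,3.31,3.71,1.06,2.37,3.33,2.74,2.63,3.34,2.92,2.61,3.20
23,2.62,1.58,2.67,1.69,-0.50,1.82,1.85,2.26,3.24,1.98,1.62,2.16,2.27
24,2.69,2.56,2.81,3.22,0.73,1.99,2.78,2.48,2.32,2.86,2.65,2.17,2.83
25,2.53,2.65,2.52,2.48,-0.12,1.89,2.40,2.34,1.80,2.34,1.89,1.56,2.41
26,2.69,2.56,2.99,3.22,0.79,1.99,2.78,2.48,2.32,2.86,2.65,2.17,2.83
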