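sample_id,group,role,LQA,LQT,LQG,GLA,ISS,ISG,P6C_pct,asae_mM,pred_asae_mM,re_pct
S1,A,training,8.470,10.034,1.621,78.446,4.040,2.263,84.204,0.2178,0.2148,-1.37
S2,A,training,8.097,9.754,1.574,73.001,3.723,2.100,79.435,0.2110,0.2030,-3.78
S3,A,test,8.714,9.659,1.726,77.484,3.712,2.433,84.002,0.2247,0.2078,-7.54
S4,A,training,9.657,10.926,1.875,82.536,3.700,2.305,87.990,0.2335,0.2293,-1.82
S5,A,training,9.624,10.892,1.884,80.195,3.584,2.308,86.982,0.2197,0.2203,0.31
S6,A,outlier,8.085,13.722,3.670,60.747,4.427,3.790,111.528,0.1365,,
S7,A,test,9.296,12.003,2.053,85.557,4.054,2.418,93.451,0.2120,0.2170,2.36
S8,A,training,9.817,11.781,1.904,83.763,4.112,2.170,90.903,0.2232,0.2228,-0.16
S9,A,training,8.080,8.412,1.951,79.059,3.521,2.755,84.559,0.1594,0.1881,18.01
S10,A,training,8.972,11.401,2.041,76.784,4.394,2.727,93.992,0.1984,0.1923,-3.07
S11,B,training,21.731,10.675,2.114,93.908,3.251,2.609,103.750,0.2793,0.2789,-0.16
S12,B,training,24.364,11.781,2.068,95.158,3.589,2.285,107.459,0.2809,0.2804,-0.17
S13,B,test,22.511,10.878,2.319,93.076,3.346,2.689,107.034,0.2504,0.2859,14.21
S14,B,training,24.314,12.040,1.847,88.789,3.457,1.846,101.505,0.2804,0.2809,0.17
S15,B,training,20.247,11.478,2.276,95.474,3.485,2.196,103.197,0.2458,0.2591,5.44
S16,B,training,20.908,10.021,2.361,88.114,3.561,3.171,107.585,0.2489,0.2530,1.64
S17,B,test,18.255,9.232,2.019,85.626,3.545,2.464,96.126,0.2148,0.2577,20.00
S18,B,outlier,13.703,11.014,5.181,77.198,4.409,4.573,131.753,0.2046,,
S19,B,test,14.741,11.101,2.485,82.361,4.174,3.134,105.205,0.1753,0.2238,27.62
S20,B,training,20.158,8.646,1.506,79.109,3.216,1.828,86.665,0.2494,0.2329,-6.62
S21,C,training,19.043,11.877,3.193,75.550,3.236,1.669,100.078,0.2250,0.2280,1.35
S22,C,training,21.414,13.321,3.362,87.217,3.520,1.717,109.792,0.2380,0.2354,-1.13
S23,C,test,21.846,13.897,3.412,89.752,3.596,1.858,113.235,0.2316,0.2482,7.19
S24,C,training,22.441,13.670,2.817,85.938,3.788,2.004,110.587,0.2555,0.2604,1.90
S25,C,training,15.160,10.320,4.952,87.349,2.959,3.292,117.473,0.2436,0.2372,-2.64
S26,C,training,20.717,11.902,2.572,76.887,3.158,1.946,99.394,0.2318,0.2394,3.26
S27,C,test,22.361,10.317,2.444,77.354,2.969,2.654,101.738,0.2291,0.2310,0.85
S28,C,training,20.628,11.224,2.822,89.800,3.272,2.816,108.860,0.2488,0.2503,0.62
S29,C,training,17.293,9.856,1.792,76.981,3.137,2.170,88.978,0.2352,0.2210,-6.02
S30,C,training,20.202,9.227,2.517,80.700,3.108,3.084,102.551,0.2360,0.2341,-0.82
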