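sample_id,channel,S_L,P_L_pct,alpha,grade
S1,203nm,0.914,56.1,0.105,7
S1,220nm,0.939,69.8,0.080,6
S1,250nm,0.952,94.8,0.018,2
S1,280nm,0.914,82.0,0.068,4
S1,344nm,0.958,76.2,0.025,5
S1,fusion,0.927,76.4,0.015,5
S2,203nm,0.889,54.2,0.093,7
S2,220nm,0.944,67.2,0.063,6
S2,250nm,0.969,88.1,0.004,3
S2,280nm,0.925,78.1,0.052,5
S2,344nm,0.957,69.8,0.023,6
S2,fusion,0.945,73.6,0.014,5
S3,203nm,0.910,55.6,0.181,7
S3,220nm,0.941,69.5,0.071,6
S3,250nm,0.963,88.6,0.119,3
S3,280nm,0.919,80.6,0.067,4
S3,344nm,0.957,73.0,0.007,5
S3,fusion,0.943,75.1,0.040,5
S4,203nm,0.900,86.5,0.178,4
S4,220nm,0.946,78.5,0.070,5
S4,250nm,0.971,97.1,0.068,2
S4,280nm,0.922,83.2,0.048,4
S4,344nm,0.961,71.5,0.021,5
S4,fusion,0.944,88.3,0.021,3
S5,203nm,0.925,87.4,0.149,3
S5,220nm,0.948,77.4,0.054,5
S5,250nm,0.973,94.2,0.082,2
S5,280nm,0.910,81.4,0.046,4
S5,344nm,0.961,69.9,0.008,6
S5,fusion,0.943,85.1,0.029,3
S6,203nm,0.816,73.7,0.088,5
S6,220nm,0.884,71.5,0.036,5
S6,250nm,0.960,74.6,0.051,5
S6,280nm,0.870,73.6,0.029,5
S6,344nm,0.897,72.0,0.059,5
S6,fusion,0.899,76.1,0.010,5
S7,203nm,0.864,85.1,0.108,3
S7,220nm,0.932,77.5,0.032,5
S7,250nm,0.979,99.2,0.119,3
S7,280nm,0.901,85.7,0.083,3
S7,344nm,0.950,74.5,0.029,5
S7,fusion,0.936,88.8,0.053,3
S8,203nm,0.892,88.5,0.093,3
S8,220nm,0.941,81.1,0.041,4
S8,250nm,0.963,101.8,0.036,1
S8,280nm,0.927,84.2,0.010,4
S8,344nm,0.959,75.7,0.035,5
S8,fusion,0.942,91.9,0.010,2
S9,203nm,0.885,48.3,0.126,8
S9,220nm,0.925,66.3,0.089,6
S9,250nm,0.964,94.9,0.014,2
S9,280nm,0.892,80.1,0.064,4
S9,344nm,0.916,66.6,0.081,6
S9,fusion,0.915,74.5,0.046,5
S10,203nm,0.894,54.4,0.085,7
S10,220nm,0.926,71.3,0.016,5
S10,250nm,0.983,91.0,0.057,2
S10,280nm,0.917,89.5,0.111,3
S10,344nm,0.950,78.7,0.000,5
S10,fusion,0.944,77.1,0.044,5
S11,203nm,0.953,133.2,0.113,6
S11,220nm,0.976,118.4,0.002,4
S11,250nm,0.989,112.2,0.029,3
S11,280nm,0.979,116.1,0.000,4
S11,344nm,0.990,110.6,0.011,3
S11,fusion,0.969,114.7,0.032,3
S12,203nm,0.965,139.1,0.089,6
S12,220nm,0.976,122.8,0.066,5
S12,250nm,0.978,116.4,0.051,4
S12,280nm,0.975,125.0,0.059,5
S12,344nm,0.981,123.0,0.063,5
S12,fusion,0.960,124.2,0.020,5
S13,203nm,0.949,139.2,0.015,6
S13,220nm,0.968,120.5,0.009,5
S13,250nm,0.985,112.1,0.003,3
S13,280nm,0.975,120.9,0.053,5
S13,344nm,0.987,119.7,0.023,4
S13,fusion,0.969,122.7,0.024,5
S14,203nm,0.946,131.2,0.123,6
S14,220nm,0.967,120.6,0.076,5
S14,250nm,0.987,106.2,0.021,2
S14,280nm,0.969,120.2,0.088,5
S14,344nm,0.974,118.6,0.089,4
S14,fusion,0.963,113.9,0.054,3
S15,203nm,0.916,129.0,0.075,5
S15,220nm,0.969,116.2,0.014,4
S15,250nm,0.964,118.4,0.077,4
S15,280nm,0.964,103.5,0.002,1
S15,344nm,0.961,97.4,0.013,1
S15,fusion,0.942,116.3,0.014,4
S16,203nm,0.931,78.5,0.040,5
S16,220nm,0.957,106.3,0.032,2
S16,250nm,0.976,105.7,0.006,2
S16,280nm,0.969,120.2,0.078,5
S16,344nm,0.954,131.4,0.098,6
S16,fusion,0.954,103.1,0.034,1
S17,203nm,0.942,81.1,0.002,4
S17,220nm,0.974,100.9,0.023,1
S17,250nm,0.987,103.8,0.012,1
S17,280nm,0.979,115.3,0.005,4
S17,344nm,0.988,117.4,0.056,4
S17,fusion,0.972,100.5,0.014,1
S18,203nm,0.836,66.2,0.273,6
S18,220nm,0.865,95.1,0.311,6
S18,250nm,0.942,98.7,0.230,5
S18,280nm,0.848,100.2,0.335,6
S18,344nm,0.876,105.8,0.233,5
S18,fusion,0.903,95.9,0.197,4
S19,203nm,0.950,65.3,0.118,6
S19,220nm,0.979,93.1,0.002,2
S19,250nm,0.977,100.5,0.025,1
S19,280nm,0.982,104.3,0.005,1
S19,344nm,0.948,96.2,0.060,2
S19,fusion,0.960,91.3,0.003,2
S20,203nm,0.940,71.9,0.038,5
S20,220nm,0.968,96.5,0.071,2
S20,250nm,0.985,95.3,0.006,1
S20,280nm,0.952,103.0,0.128,3
S20,344nm,0.957,117.9,0.059,4
S20,fusion,0.961,93.3,0.043,2
S21,203nm,0.944,107.0,0.031,2
S21,220nm,0.976,105.6,0.084,2
S21,250nm,0.954,91.8,0.058,2
S21,280nm,0.917,80.1,0.035,4
S21,344nm,0.971,97.7,0.031,1
S21,fusion,0.946,96.5,0.001,2
S22,203nm,0.947,127.5,0.043,5
S22,220nm,0.978,116.0,0.094,4
S22,250nm,0.919,105.2,0.084,2
S22,280nm,0.919,92.2,0.000,2
S22,344nm,0.976,106.1,0.037,2
S22,fusion,0.930,110.9,0.000,3
S23,203nm,0.953,123.4,0.047,5
S23,220nm,0.973,119.4,0.116,4
S23,250nm,0.976,105.3,0.062,2
S23,280nm,0.917,91.7,0.005,2
S23,344nm,0.975,109.3,0.033,2
S23,fusion,0.953,106.6,0.082,2
S24,203nm,0.952,135.4,0.064,6
S24,220nm,0.968,121.4,0.046,5
S24,250nm,0.969,102.0,0.031,1
S24,280nm,0.926,96.4,0.009,2
S24,344nm,0.950,118.9,0.035,4
S24,fusion,0.956,114.3,0.015,3
S25,203nm,0.944,116.8,0.058,4
S25,220nm,0.950,98.7,0.073,2
S25,250nm,0.978,102.8,0.058,2
S25,280nm,0.948,90.1,0.115,3
S25,344nm,0.979,87.4,0.051,3
S25,fusion,0.964,103.3,0.037,1
S26,203nm,0.951,116.3,0.104,4
S26,220nm,0.973,109.1,0.076,2
S26,250nm,0.964,93.3,0.042,2
S26,280nm,0.921,85.5,0.054,3
S26,344nm,0.976,100.6,0.012,1
S26,fusion,0.954,101.0,0.003,1
S27,203nm,0.928,132.7,0.071,6
S27,220nm,0.952,112.1,0.027,3
S27,250nm,0.981,93.7,0.018,2
S27,280nm,0.906,85.2,0.117,3
S27,344nm,0.977,108.9,0.049,2
S27,fusion,0.949,107.2,0.032,2
S28,203nm,0.928,125.1,0.059,5
S28,220nm,0.967,116.0,0.013,4
S28,250nm,0.983,106.8,0.040,2
S28,280nm,0.915,87.3,0.218,5
S28,344nm,0.982,105.7,0.053,2
S28,fusion,0.960,113.2,0.001,3
S29,203nm,0.949,73.1,0.052,5
S29,220nm,0.965,95.1,0.001,1
S29,250nm,0.981,92.6,0.008,2
S29,280nm,0.934,87.2,0.063,3
S29,344nm,0.974,101.8,0.088,2
S29,fusion,0.955,89.9,0.023,3
S30,203nm,0.935,78.7,0.037,5
S30,220nm,0.961,103.5,0.013,1
S30,250nm,0.982,98.1,0.030,1
S30,280nm,0.894,91.8,0.101,3
S30,344nm,0.961,115.8,0.072,4
S30,fusion,0.952,97.7,0.016,1
RFP,203nm,1.000,100.0,0.000,1
RFP,220nm,1.000,100.0,0.000,1
RFP,250nm,1.000,100.0,0.000,1
RFP,280nm,1.000,100.0,0.000,1
RFP,344nm,1.000,100.0,0.000,1
RFP,fusion,1.000,100.0,0.000,1
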