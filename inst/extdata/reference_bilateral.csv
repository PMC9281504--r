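parameter,racket_d_mean,racket_d_sd,racket_nd_mean,racket_nd_sd,d_racket,noracket_d_mean,noracket_d_sd,noracket_nd_mean,noracket_nd_sd,d_noracket,f_condition,p_condition,eta2p_condition,f_side,p_side,eta2p_side,f_interaction,p_interaction,eta2p_interaction
po_peak,112.53,63.74,105.00,51.43,0.130,104.78,65.87,95.98,55.43,0.145,4.879,0.028,0.025,6.298,0.013,0.032,0.252,0.616,0.001
mz_peak,22.24,8.21,21.61,8.76,0.074,20.55,10.53,19.56,10.22,0.095,7.049,0.009,0.036,5.680,0.018,0.029,0.343,0.559,0.002
ftot_peak,117.77,45.36,86.53,40.75,0.725,86.53,38.65,73.75,38.81,0.330,32.738,<0.001,0.148,123.513,<0.001,0.395,12.211,<0.001,0.061
fef,29.36,6.93,40.85,14.15,1.031,35.82,10.94,41.14,13.14,0.440,33.888,<0.001,0.152,124.709,<0.001,0.398,25.260,<0.001,0.118
ror,587.42,305.96,388.64,228.52,0.736,388.65,210.90,289.02,181.49,0.506,43.815,<0.001,0.188,118.824,<0.001,0.386,1.765,0.186,0.009
ai,4.01,2.00,4.00,2.19,0.005,4.25,2.41,4.10,2.44,0.062,0.102,0.750,0.001,0.286,0.594,0.002,1.191,0.276,0.006
pt,0.34,0.10,0.34,0.08,0.000,0.36,0.07,0.37,0.07,0.143,12.254,<0.001,0.061,0.003,0.955,0.000,0.004,0.950,0.000
ct,1.13,0.43,1.11,0.39,0.049,1.29,0.45,1.30,0.45,0.022,12.797,<0.001,0.063,0.394,0.531,0.002,0.685,0.409,0.004
pa,84.68,30.47,83.22,19.44,0.057,90.98,19.60,91.06,19.23,0.004,10.886,0.001,0.054,0.196,0.659,0.001,0.043,0.836,0.000
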