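parameter,with_mean,with_sd,without_mean,without_sd,t,p,d
po_peak,112.53,63.74,104.78,65.87,1.867,0.032,0.120
mz_peak,22.24,8.21,20.55,10.53,2.356,0.010,0.179
ftot_peak,117.77,45.36,86.53,38.65,7.530,<0.001,0.741
fef,29.36,6.93,35.82,10.94,8.197,<0.001,0.705
ror,587.42,305.96,388.65,210.90,7.597,<0.001,0.756
ai,4.01,2.00,4.25,2.41,0.330,0.371,0.108
pt,0.34,0.10,0.36,0.07,3.086,0.001,0.231
ct,1.13,0.43,1.29,0.45,3.134,<0.001,0.363
pa,84.68,30.47,90.98,19.60,2.555,0.006,0.246
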