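group,n,lsas_mean,lsas_sd,bias_mean,bias_sd
2D-mock,23,71.00,20.02,-6.07,32.94
2D-active,25,68.68,18.24,3.13,29.72
3D-mock,23,70.35,18.02,14.52,43.22
3D-active,24,69.00,21.86,-4.45,39.17
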