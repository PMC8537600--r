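class,d_mean_um,d_sd_um,ri_cytosol,ri_nucleus,nc_ratio
CTC,18.44,3.49,1.36,1.40,0.920
RBC,7.64,0.91,1.40,NA,1.00
T,6.60,0.36,1.36,1.40,0.950
B,7.42,0.51,1.36,1.42,0.975
M,9.57,1.02,1.36,1.38,0.784
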