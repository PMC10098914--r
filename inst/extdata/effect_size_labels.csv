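metric,setting,estimator,gamma,magnitude
rmse,contact,RR_avg,0.000,negligible
rmse,contact,RR_median,-0.079,negligible
rmse,contact,RR_PCA,-0.269,small
rmse,contact,RR_RIFV,-0.531,medium
rmse,contact,RR_RIIV,-0.233,small
rmse,contact,RR_RIAV,-0.473,small
rmse,contact,RR_EMD,-1.727,large
rmse,contact,RR_IMF1,-2.765,large
rmse,contact,RR_IMF2,-0.647,medium
rmse,contact,RR_IMF3,-3.068,large
rmse,contact,RR_SSA,-1.163,large
rmse,contact,RR_EOF1,-1.509,large
rmse,contact,RR_EOF2,-1.407,large
rmse,contact,RR_EOF3,-1.658,large
rmse,remote,RR_avg,0.000,negligible
rmse,remote,RR_median,-0.204,small
rmse,remote,RR_PCA,-0.493,small
rmse,remote,RR_RIFV,-0.571,medium
rmse,remote,RR_RIIV,-0.472,small
rmse,remote,RR_RIAV,-0.567,medium
rmse,remote,RR_EMD,-1.367,large
rmse,remote,RR_IMF1,-1.539,large
rmse,remote,RR_IMF2,-1.128,large
rmse,remote,RR_IMF3,-2.982,large
rmse,remote,RR_SSA,-1.489,large
rmse,remote,RR_EOF1,-1.474,large
rmse,remote,RR_EOF2,-0.751,medium
rmse,remote,RR_EOF3,-3.737,large
mae,contact,RR_avg,0.039,negligible
mae,contact,RR_median,0.000,negligible
mae,contact,RR_PCA,-0.117,negligible
mae,contact,RR_RIFV,-0.442,small
mae,contact,RR_RIIV,-0.124,negligible
mae,contact,RR_RIAV,-0.270,small
mae,contact,RR_EMD,-1.464,large
mae,contact,RR_IMF1,-2.448,large
mae,contact,RR_IMF2,-0.515,medium
mae,contact,RR_IMF3,-3.102,large
mae,contact,RR_SSA,-0.919,large
mae,contact,RR_EOF1,-1.132,large
mae,contact,RR_EOF2,-1.082,large
mae,contact,RR_EOF3,-1.503,large
mae,remote,RR_avg,0.000,negligible
mae,remote,RR_median,-0.064,negligible
mae,remote,RR_PCA,-0.298,small
mae,remote,RR_RIFV,-0.392,small
mae,remote,RR_RIIV,-0.330,small
mae,remote,RR_RIAV,-0.352,small
mae,remote,RR_EMD,-1.115,large
mae,remote,RR_IMF1,-1.342,large
mae,remote,RR_IMF2,-1.117,large
mae,remote,RR_IMF3,-3.085,large
mae,remote,RR_SSA,-1.499,large
mae,remote,RR_EOF1,-1.420,large
mae,remote,RR_EOF2,-0.501,medium
mae,remote,RR_EOF3,-3.345,large
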