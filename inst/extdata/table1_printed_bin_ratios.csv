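bin_label,week,ratio_hsc_lsc,q_fdr
7.93,14,1.53,
7.93,22,1.41,
1.52,14,0.76,
1.52,22,0.78,
0.88,14,0.65,
0.88,22,0.75,
2.18,14,0.81,
2.18,22,0.86,
1.06,14,0.73,
1.06,22,0.73,
0.84,14,0.84,
0.84,22,1.37,
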