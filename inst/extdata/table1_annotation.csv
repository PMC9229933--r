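bin_label,metabolite,origin,tentative,shared
7.93,Xanthine,diet,FALSE,FALSE
1.52,Butyrate,microbiome,FALSE,FALSE
0.88,Butyrate,microbiome,FALSE,FALSE
2.18,Butyrate,microbiome,FALSE,TRUE
2.18,Propionate,microbiome,FALSE,TRUE
1.06,Propionate,microbiome,FALSE,FALSE
5.62,UDP-glucose,microbiome,FALSE,FALSE
5.63,UDP-glucose,microbiome,FALSE,FALSE
5.64,UDP-glucose,microbiome,FALSE,FALSE
0.84,Valerate,microbiome,TRUE,FALSE
5.94,Uridine derivates,microbiome,FALSE,FALSE
6.11,Uridine derivates,microbiome,FALSE,FALSE
6.12,Uridine derivates,microbiome,FALSE,FALSE
6.13,Uridine derivates,microbiome,FALSE,FALSE
7.86,Uridine derivates,microbiome,FALSE,FALSE
7.89,Uridine derivates,microbiome,FALSE,FALSE
0.73,Bile acids,endogenous,TRUE,FALSE
0.74,Bile acids,endogenous,TRUE,FALSE
0.75,Bile acids,endogenous,TRUE,FALSE
0.76,Bile acids,endogenous,TRUE,FALSE
0.77,Bile acids,endogenous,TRUE,FALSE
6.65,Kynurenic acid,endogenous,FALSE,FALSE
7.49,Kynurenic acid,endogenous,FALSE,FALSE
7.68,Kynurenic acid,endogenous,FALSE,FALSE
7.82,Kynurenic acid,endogenous,FALSE,FALSE
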