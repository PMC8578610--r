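response,predictor,estimate,se,printed_odds_ratio
sebastidae,max_depth_m,1.03e-02,3.83e-03,NA
sebastidae,max_depth_m2,-2.15e-05,9.91e-06,NA
sebastidae,ABU,-7.38e-02,0.56,1.08
sebastidae,EQCS,5.88e-01,2.17e-01,0.56
coral,max_depth_m,2.83e-02,4.75e-03,NA
coral,max_depth_m2,-4.16e-05,1.01e-05,NA
coral,EQCS,6.14e-01,4.74e-01,1.85
sponge,max_depth_m,2.97e-02,1.03e-02,NA
sponge,max_depth_m2,-1.48e-04,5.75e-05,NA
sponge,EQCS,-1.48,0.35,4.39
overall,max_depth_m,2.00e-02,4.27e-03,NA
overall,max_depth_m2,-4.70e-05,1.19e-05,NA
overall,EQCS,-1.09,0.33,2.97
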