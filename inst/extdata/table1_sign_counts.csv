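sign,tp,fn,fp,tn,auc,accuracy,ppv,npv,sensitivity,specificity
solid_nodule,32,24,63,97,0.589,0.60,0.34,0.80,NA,NA
irregular_shape,27,29,108,52,0.404,0.37,0.20,0.64,0.48,0.33
cystic_airspaces,13,43,65,95,0.413,0.50,0.17,0.69,0.23,0.59
unclear_interface,38,18,52,108,0.677,0.68,0.42,0.86,0.68,0.68
satellites,14,42,6,154,0.606,0.78,0.70,0.79,0.25,0.96
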