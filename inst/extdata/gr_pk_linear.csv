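drug,CL_L_per_h,Vc_L,Vp_L,Q_L_per_h,ka_per_min,F,fu,MW,iv_salt,MW_salt,param_status
dexamethasone,12,30,40,15,0.015,0.59,0.23,392.5,phosphate,472.4,placeholder_except_F_fu_MW
methylprednisolone,24,25,45,30,0.02,0.85,0.23,374.5,none,NA,placeholder_except_fu_MW
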