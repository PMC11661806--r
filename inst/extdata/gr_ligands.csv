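ligand,Kc_nM,Kn_nM,KmT_nM,KmL_printed_nM,KmL_flag,source
dexamethasone,5,155,5,0.00079,ok,reference affinity table
cortisol,75,1550,50,0.0118,ok,reference affinity table
prednisolone,15,465,15,0.0044,suspected_erratum,reference affinity table
methylprednisolone,15,465,15,0.00236,ok,reference affinity table
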