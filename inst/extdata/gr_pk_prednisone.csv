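param,value,units,description,param_status
ka_per_min,0.02,min^-1,oral absorption rate of prednisone,placeholder
F,0.8,fraction,oral bioavailability of prednisone,placeholder
V_pred_L,50,L,distribution volume for total plasma prednisone,placeholder
V_prednisolone_L,35,L,distribution volume for total plasma prednisolone,placeholder
fu_pred,0.3,fraction,free fraction of prednisone (linear binding),placeholder
CL_pred_L_per_min,1.0,L/min,intrinsic clearance of free prednisone (excl. conversion),placeholder
f_firstpass,0.78,fraction,fraction of absorbed dose converted to prednisolone on first pass,placeholder
CL_conv_L_per_min,2.0,L/min,intrinsic conversion clearance free prednisone -> prednisolone,placeholder
CL_back_L_per_min,1.1,L/min,intrinsic back-conversion clearance free prednisolone -> prednisone,placeholder
CL_prednisolone_L_per_min,1.0,L/min,intrinsic clearance of free prednisolone,placeholder
transcortin_Bmax_nM,300,nM,saturable transcortin binding capacity,placeholder
transcortin_Kd_nM,50,nM,transcortin-prednisolone dissociation constant,placeholder
NS_bound_per_free,4,ratio,linear (albumin-like) bound:free ratio for prednisolone,placeholder
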