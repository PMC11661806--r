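cell_line,KmT_dex_nM,rel_cortisol,rel_methylprednisolone,rel_prednisolone,ref
AZ-GR,9.55,6.91,3.16,4.67,30
HeLa,12,11,3.33,3.33,36
A549,10,15,4,7,36
HTC,4,15,5,5,36
GR-LBD,0.154,30.9,2.87,NA,37
PBMC,4.1,NA,3.36,21,38
CCL-202,0.5,20,NA,10,39
GR/3xGRE,1.66,27.5,NA,NA,40
GR/MMTV,1.02,58.9,NA,NA,40
GR-LBD.2,0.83,72.4,NA,NA,40
Clone #1,2.82,NA,NA,5.37,28
Clone #5,5.89,NA,NA,4.79,28
Clone #6,8.71,NA,NA,3.98,28
A549.2,1,10,NA,NA,28
Hepatocytes,10,NA,NA,NA,31
GR(WT),0.5,NA,NA,NA,31
GR(ER22),8,NA,NA,NA,31
AR42,10,NA,NA,NA,31
Human clinical response,NA,25,5,6.25,35
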