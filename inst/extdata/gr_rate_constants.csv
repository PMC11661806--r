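param,value,units,description
k1,10,min^-1,cytoplasmic loose-to-tight binding conversion RcG->RcGt
k2,0.2,min^-1,nuclear import RcGt->RnGt
k3,0.2,min^-1,activation RnGt->RnGN
k4,0.04,min^-1,dissociation/recycle RnGN->Rn
k5,0.0017,min^-1,nuclear export Rn->Rc
k6,1.0,min^-1,nuclear loose-to-tight binding conversion RnG->RnGt
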