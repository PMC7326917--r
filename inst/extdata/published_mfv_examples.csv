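germplasm,MFV_GR,MFV_GI,MFV_GE,MFV_RL,MFV_GVI,MFV_FW,MFV_WC,mean_MFV,grade
152505,0.936,0.856,0.719,0.343,0.488,0.905,0.758,0.715,HST
156004,0.933,0.681,0.323,0.602,0.681,0.841,0.756,0.688,HST
156017,0.913,0.652,0.340,0.672,0.728,0.751,0.685,0.677,HST
151082,1.000,1.000,1.000,0.177,0.294,0.660,0.539,0.667,HST
151040,0.633,0.635,0.639,0.876,0.925,0.260,0.580,0.650,HST
152012,0.030,0.002,0.000,0.085,0.000,0.000,0.000,0.017,HSS
152021,0.000,0.000,0.000,0.000,0.000,0.000,0.000,0.000,HSS
152094,0.000,0.000,0.000,0.000,0.000,0.000,0.000,0.000,HSS
156084,0.000,0.000,0.000,0.000,0.000,0.000,0.000,0.000,HSS
156096,0.000,0.000,0.000,0.000,0.000,0.000,0.000,0.000,HSS
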