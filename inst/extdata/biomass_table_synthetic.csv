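standard,V_mean,V_sd,is_bead
AJH,1.20,0.30,FALSE
ECL1,0.80,0.20,FALSE
ECL2,0.90,0.20,FALSE
PVR1,1.60,0.40,FALSE
PVR2,1.40,0.35,FALSE
B02,0.0000042,0,TRUE
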