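ion,dVdT_1e3,dVdT_se_1e3,d2VdT2_1e3,d2VdT2_se_1e3,T_extr
H,-16.5,NA,-0.17,NA,-24
Li,-31.8,5.5,0.56,0.49,53
Na,44.7,5.9,-0.3,0.51,Inf
K,17.1,5.9,1.31,0.51,18
Mg,-57.6,10.6,1.49,0.93,44
Cl,35.8,4.3,-1.5,0.38,37
Br,57.2,5.6,-1.47,0.5,44
I,89.9,5.6,-2.62,0.49,42
SO4,124.4,11.1,-3.61,0.97,42
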