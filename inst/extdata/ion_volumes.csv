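ion,T,V,SE
H,20,-5.33,NA
H,25,-5.41,NA
H,30,-5.49,NA
H,35,-5.59,NA
H,40,-5.69,NA
Li,20,-5.44,0.22
Li,25,-5.56,0.21
Li,30,-5.72,0.2
Li,35,-5.9,0.21
Li,40,-5.91,0.25
Na,20,-6.2,0.24
Na,25,-5.91,0.22
Na,30,-5.74,0.22
Na,35,-5.57,0.22
Na,40,-5.32,0.26
K,20,4.32,0.24
K,25,4.48,0.22
K,30,4.52,0.22
K,35,4.65,0.22
K,40,5.01,0.26
Mg,20,-27.07,0.43
Mg,25,-27.26,0.4
Mg,30,-27.59,0.39
Mg,35,-27.86,0.41
Mg,40,-27.81,0.47
Cl,20,22.67,0.18
Cl,25,22.85,0.16
Cl,30,23.03,0.16
Cl,35,23.09,0.17
Cl,40,23.07,0.19
Br,20,29.68,0.23
Br,25,29.96,0.21
Br,30,30.25,0.21
Br,35,30.41,0.22
Br,40,30.51,0.25
I,20,40.59,0.23
I,25,41.06,0.21
I,30,41.48,0.21
I,35,41.75,0.22
I,40,41.83,0.25
SO4,20,22.63,0.45
SO4,25,23.24,0.41
SO4,30,23.81,0.41
SO4,35,24.28,0.42
SO4,40,24.3,0.49
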