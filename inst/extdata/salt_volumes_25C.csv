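solute,order,V,V_se,alpha_1e3,alpha_se_1e3,beta_1e3,beta_se_1e3,T_extr
LiCl,linear,17.85,0.09,-3,10,NA,NA,NA
NaCl,linear,16.37,0.09,61,11,NA,NA,NA
KCl,linear,27.19,0.11,61,14,NA,NA,NA
MgCl2,linear,18.09,0.13,-10,16,NA,NA,NA
LiBr,linear,24.01,0.08,20,9,NA,NA,NA
NaBr,linear,23.16,0.12,89,15,NA,NA,NA
KBr,linear,33.53,0.14,77,17,NA,NA,NA
MgBr2,linear,33.18,0.11,40,12,NA,NA,NA
LiI,linear,35.7,0.08,32,9,NA,NA,NA
NaI,linear,35.86,0.11,108,13,NA,NA,NA
KI,linear,44.66,0.11,91,12,NA,NA,NA
MgI2,linear,54.62,0.14,89,16,NA,NA,NA
Li2SO4,linear,11.83,0.1,36,11,NA,NA,NA
Na2SO4,linear,11.2,0.17,171,21,NA,NA,NA
K2SO4,linear,33.37,0.1,142,12,NA,NA,NA
MgSO4,linear,-4.74,0.1,58,12,NA,NA,NA
HCl,linear,17.7,0.05,6,6,NA,NA,NA
LiCl,quadratic,17.89,0.1,13,20,-1.6,1.8,31
NaCl,quadratic,16.43,0.12,87,25,-2.6,2.2,29
KCl,quadratic,27.22,0.18,66,36,0,3.1,42
MgCl2,quadratic,18.06,0.2,-4,41,-0.5,3.5,32
LiBr,quadratic,24.03,0.09,26,18,-0.6,1.6,38
NaBr,quadratic,23.21,0.18,106,37,-1.5,3.2,47
KBr,quadratic,33.54,0.21,83,43,-0.2,3.7,59
MgBr2,quadratic,33.15,0.12,55,24,-1.6,2.1,Inf
LiI,quadratic,35.75,0.09,50,18,-1.8,1.6,33
NaI,quadratic,35.9,0.13,123,26,-1.5,2.2,39
KI,quadratic,44.71,0.12,113,24,-2.2,2.1,65
MgI2,quadratic,54.72,0.16,129,32,-4.1,2.7,51
Li2SO4,quadratic,11.89,0.11,60,22,-2.4,1.9,41
Na2SO4,quadratic,11.3,0.25,221,52,-5.5,4.5,37
K2SO4,quadratic,33.32,0.14,145,28,-0.1,2.5,45
MgSO4,quadratic,-4.71,0.11,73,25,-1.5,2.2,Inf
HCl,quadratic,17.69,0.07,21,13,-1.7,1.2,45
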