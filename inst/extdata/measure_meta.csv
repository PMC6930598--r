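measure_id,source,anova_class
logP_ChemDraw,software,Comp_F
ClogP_ChemDraw,software,Comp_F
VlogP,software,Comp_P
logPC_Spartan,software,Comp_F
logPV_Spartan,software,Comp_F
miLogP,software,Comp_F
logP_KOWWIN,software,Comp_M
AlogPs,software,Comp_P
AClogP,software,Comp_A
AlogP,software,Comp_F
MlogP,software,Comp_P
XlogP2,software,Comp_A
XlogP3,software,Comp_A
B3LYP_631Gp,dft,Comp_DFT
B3LYP_6311Gppdp,dft,Comp_DFT
CAMB3LYP_6311Gppdp,dft,Comp_DFT
wB97XD_6311Gppdp,dft,Comp_DFT
PBE0_6311Gppdp,dft,Comp_DFT
PBE0_6311Gpp2df2dp,dft,Comp_DFT
C8_RM0,tlc_c8,TLC_C8
C8_m,tlc_c8,TLC_C8
C8_C0,tlc_c8,TLC_C8
C8_mRM,tlc_c8,TLC_C8
C8_PC1,tlc_c8,TLC_C8
C18_RM0,tlc_c18,TLC_C18
C18_m,tlc_c18,TLC_C18
C18_C0,tlc_c18,TLC_C18
C18_mRM,tlc_c18,TLC_C18
C18_PC1,tlc_c18,TLC_C18
HPLC_logkw,hplc,HPLC_C18
MEKC_logk,mekc,MEKC
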