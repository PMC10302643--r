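# Hammett sigma constants for common aryl substituents.
# Numeric source: Hansch, Leo and Taft, "A survey of Hammett substituent
# constants and resonance and field parameters", Chem. Rev. 1991, 91, 165-195.
# Columns: substituent symbol, sigma_meta, sigma_para (dimensionless).
substituent,sigma_meta,sigma_para
H,0.00,0.00
Me,-0.07,-0.17
Et,-0.07,-0.15
tBu,-0.10,-0.20
Ph,0.06,-0.01
OMe,0.12,-0.27
OH,0.12,-0.37
OCF3,0.38,0.35
NH2,-0.16,-0.66
NMe2,-0.16,-0.83
F,0.34,0.06
Cl,0.37,0.23
Br,0.39,0.23
I,0.35,0.18
CF3,0.43,0.54
CN,0.56,0.66
NO2,0.71,0.78
Ac,0.38,0.50
CHO,0.35,0.42
CO2Me,0.37,0.45
CONH2,0.28,0.36
SMe,0.15,0.00
SO2Me,0.60,0.72
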