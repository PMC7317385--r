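method,VDD,Hirshfeld,HLY,ISA,DDEC6,MBIS,HirshfeldI,MBSBickelhaupt,NPA,IBO,MBSMulliken,iACP,ACP,CM5,EEQ,QTAIM,APT,ADCH
VDD,1.00,0.96,0.64,0.78,0.81,0.77,0.78,0.78,0.74,0.78,0.70,0.78,0.78,0.76,0.73,0.64,0.68,0.68
Hirshfeld,0.96,1.00,0.67,0.79,0.85,0.80,0.80,0.79,0.78,0.82,0.76,0.75,0.80,0.78,0.73,0.61,0.62,0.72
HLY,0.64,0.67,1.00,0.87,0.84,0.84,0.79,0.76,0.73,0.73,0.72,0.71,0.77,0.73,0.70,0.48,0.51,0.68
ISA,0.78,0.79,0.87,1.00,0.94,0.94,0.92,0.89,0.81,0.80,0.77,0.89,0.85,0.78,0.77,0.69,0.74,0.69
DDEC6,0.81,0.85,0.84,0.94,1.00,0.99,0.98,0.94,0.92,0.91,0.90,0.85,0.89,0.84,0.81,0.66,0.67,0.75
MBIS,0.77,0.80,0.84,0.94,0.99,1.00,0.97,0.95,0.93,0.89,0.90,0.86,0.90,0.84,0.82,0.66,0.66,0.74
HirshfeldI,0.78,0.80,0.79,0.92,0.98,0.97,1.00,0.94,0.92,0.89,0.88,0.87,0.86,0.80,0.78,0.74,0.73,0.68
MBSBickelhaupt,0.78,0.79,0.76,0.89,0.94,0.95,0.94,1.00,0.92,0.87,0.90,0.89,0.92,0.87,0.86,0.75,0.71,0.71
NPA,0.74,0.78,0.73,0.81,0.92,0.93,0.92,0.92,1.00,0.96,0.98,0.73,0.85,0.84,0.81,0.60,0.55,0.73
IBO,0.78,0.82,0.73,0.80,0.91,0.89,0.89,0.87,0.96,1.00,0.96,0.71,0.81,0.82,0.80,0.56,0.55,0.75
MBSMulliken,0.70,0.76,0.72,0.77,0.90,0.90,0.88,0.90,0.98,0.96,1.00,0.68,0.84,0.85,0.83,0.52,0.49,0.76
iACP,0.78,0.75,0.71,0.89,0.85,0.86,0.87,0.89,0.73,0.71,0.68,1.00,0.88,0.77,0.77,0.84,0.83,0.59
ACP,0.78,0.80,0.77,0.85,0.89,0.90,0.86,0.92,0.85,0.81,0.84,0.88,1.00,0.91,0.89,0.63,0.60,0.75
CM5,0.76,0.78,0.73,0.78,0.84,0.84,0.80,0.87,0.84,0.82,0.85,0.77,0.91,1.00,0.97,0.51,0.48,0.81
EEQ,0.73,0.73,0.70,0.77,0.81,0.82,0.78,0.86,0.81,0.80,0.83,0.77,0.89,0.97,1.00,0.54,0.50,0.76
QTAIM,0.64,0.61,0.48,0.69,0.66,0.66,0.74,0.75,0.60,0.56,0.52,0.84,0.63,0.51,0.54,1.00,0.86,0.36
APT,0.68,0.62,0.51,0.74,0.67,0.66,0.73,0.71,0.55,0.55,0.49,0.83,0.60,0.48,0.50,0.86,1.00,0.36
ADCH,0.68,0.72,0.68,0.69,0.75,0.74,0.68,0.71,0.73,0.75,0.76,0.59,0.75,0.81,0.76,0.36,0.36,1.00
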