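method,pc1,pc2,pc3,pc4,pc5,pc6
VDD,-0.08,0.00,-0.01,0.15,0.22,-0.26
Hirshfeld,-0.08,0.02,-0.02,0.12,0.18,-0.27
CHELPG,-0.21,0.01,0.37,0.04,-0.03,-0.03
MK,-0.21,0.11,0.39,-0.08,-0.11,-0.08
RESP,-0.21,0.10,0.37,-0.05,-0.09,-0.11
HLY,-0.22,0.20,0.38,-0.16,-0.28,-0.14
ISA,-0.23,0.03,0.21,-0.07,0.14,0.12
DDEC6,-0.21,0.09,-0.01,-0.09,0.10,0.10
MBIS,-0.26,0.11,-0.02,-0.13,0.02,0.32
HirshfeldI,-0.26,0.03,-0.08,-0.23,0.06,0.22
MBSBickelhaupt,-0.26,0.02,-0.14,0.12,-0.08,0.25
NPA,-0.28,0.20,-0.35,-0.22,-0.05,0.01
IBO,-0.21,0.17,-0.23,-0.16,0.16,-0.35
MBSMulliken,-0.28,0.29,-0.37,-0.15,-0.07,-0.08
iACP,-0.20,-0.13,0.07,0.28,0.09,0.32
ACP,-0.14,0.06,-0.02,0.31,0.01,0.21
CM5,-0.14,0.13,-0.05,0.43,0.01,0.10
EEQ,-0.14,0.11,-0.06,0.46,-0.02,0.09
QTAIM,-0.38,-0.72,-0.18,0.05,-0.47,-0.24
APT,-0.24,-0.40,0.09,-0.14,0.71,-0.02
ADCH,-0.13,0.20,-0.02,0.37,0.12,-0.49
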