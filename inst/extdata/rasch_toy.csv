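person,I1,I2,I3,I4,I5
P1,1,1,1,1,1
P2,1,1,1,1,1
P3,0,1,0,0,1
P4,0,1,0,0,0
P5,0,0,0,0,1
P6,0,0,1,0,1
P7,1,1,1,1,1
P8,0,1,0,0,1
P9,0,0,0,0,1
P10,0,0,0,1,0
P11,0,0,0,1,1
P12,1,1,1,1,0
P13,0,0,1,0,0
P14,0,1,0,1,0
P15,1,1,0,1,1
P16,0,0,0,0,0
P17,0,0,1,1,0
P18,0,0,1,0,0
P19,1,0,1,0,0
P20,1,1,0,1,1
P21,0,0,0,1,0
P22,1,1,1,1,0
P23,1,1,0,1,0
P24,1,1,1,1,0
P25,1,1,1,1,1
P26,1,1,0,1,1
P27,1,1,1,1,0
P28,0,0,1,1,0
P29,1,0,0,0,1
P30,1,1,0,1,1
P31,0,1,1,1,0
P32,0,0,0,0,0
P33,0,1,1,1,1
P34,1,1,1,1,1
P35,0,0,1,1,0
P36,1,1,0,0,0
P37,1,1,1,1,1
P38,1,0,1,1,1
P39,1,0,0,1,0
P40,0,0,0,0,1
P41,0,0,1,0,1
P42,0,1,0,0,1
P43,0,0,1,1,0
P44,1,0,1,1,0
P45,1,0,1,0,0
P46,1,0,1,1,1
P47,1,1,1,0,1
P48,1,0,0,1,1
P49,0,0,0,1,0
P50,1,1,1,1,0
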