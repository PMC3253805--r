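label,group
A,stem
B,I
B1,I
B2,I
B3,I
B4,I
C,V
C1,V
C2,V
C3,V
C4,V
C5,V
C6,V
C7,V
C8,V
C9,V
D,II
D1,II
E1,III
E2,III
E3,III
E4,III
F,IV
F1,IV
F2,IV
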