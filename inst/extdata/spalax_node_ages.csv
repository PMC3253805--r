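label,mean,low,high
A,19.9531,12.8489,27.4378
B,7.5651,6.4697,8.7122
B1,2.6704,1.8574,3.4955
B2,1.3621,0.8076,1.9249
B3,1.6372,1.1114,2.2343
B4,0.9794,0.6006,1.3742
C,4.6802,3.4944,5.8574
C1,2.3488,1.7264,3.12
C2,1.4852,1.0657,1.9921
C3,0.5153,0.29,0.7944
C4,1.2263,0.8444,1.6299
C5,0.4875,0.3021,0.6641
C6,0.0244,0.0015,0.054
C7,0.5191,0.3068,0.7328
C8,0.1461,0.0706,0.225
C9,0.0596,0.0258,0.0957
D,3.1132,2.2517,3.9619
D1,0.403,0.2547,0.5705
E1,1.81,1.1933,2.3856
E2,0.7569,0.4725,1.0847
E3,0.3684,0.2006,0.5535
E4,0.0458,0.0121,0.0896
F,1.7751,1.2558,2.3223
F1,0.0662,0.0206,0.1209
F2,0.9523,0.5896,1.3693
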