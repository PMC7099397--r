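subject,rhythm,beats,acc_rnn,ppv_rnn,sen_rnn,spec_rnn,acc_fused,ppv_fused,sen_fused,spec_fused
100,Normal,2273,99.74,99.34,99.34,99.84,99.91,99.78,99.78,99.95
104,Paced,2225,98.04,95.10,95.10,98.78,99.12,97.80,97.80,99.45
108,Normal,1756,97.56,93.91,93.91,98.48,99.66,99.15,99.15,99.79
202,Afib,2133,98.87,97.19,97.19,99.30,99.51,98.78,98.78,99.70
223,VT,2604,97.45,93.63,93.63,98.41,98.54,96.35,96.35,99.09
12006,Normal,60867,99.87,99.66,99.66,99.92,99.90,99.76,99.76,99.94
12007,Normal,75805,99.87,99.66,99.66,99.92,99.99,99.97,99.97,99.99
12008,Normal,78866,99.94,99.84,99.84,99.96,99.98,99.96,99.96,99.99
12010,SVT and VT,75914,99.89,99.72,99.72,99.93,99.97,99.94,99.94,99.98
12011,Bigeminy,66229,99.92,99.79,99.79,99.95,99.71,99.27,99.27,99.82
12012,Normal,63820,99.98,99.94,99.94,99.99,99.99,99.99,99.99,99.99
12358,Noise,85091,99.97,99.92,99.92,99.98,99.96,99.90,99.90,99.97
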