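name	phosphosites
P2Nterm	S16,S21,S26,S27,S30,S33,S34,T38,S44
P1Nterm	S16,S21,T22,S33,S35
P2L1	T154,T158,T161,S164,T166,T167,S171
P1L1	S156,S159,S167
P2L2	T298,S308
P1L2	S341
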