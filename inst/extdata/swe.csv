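subject,position,modulus_MPa
S1,B,0.001975
S1,C,0.002145
S2,B,0.002678
S2,C,0.003273
S3,B,0.0037
S3,C,0.0018
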