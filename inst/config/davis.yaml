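preset: davis
l_d: 36
l_p: 900
e_d: 64
L_d: 2
L_p: 1
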