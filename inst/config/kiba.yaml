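preset: kiba
l_d: 80
l_p: 800
e_d: 128
L_d: 2
L_p: 2
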