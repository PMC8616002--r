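residue,pka,polarity
D,3.9,acid
E,4.1,acid
C,8.5,acid
Y,10.1,acid
Cterm,3.6,acid
H,6.5,base
K,10.8,base
R,12.5,base
Nterm,8.6,base
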