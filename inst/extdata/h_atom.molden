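[Molden Format]
[Title]
 written by lapnet
[Atoms] AU
H      1    1  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00
[GTO]
   1 0
 s    1 1.00
   1.0000000000000000e+00  1.0000000000000000e+00

[MO]
 Sym= A
 Ene= 1
 Spin= Alpha
 Occup=  2.0000000000000000e+00
     1  1.0000000000000000e+00
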