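[Molden Format]
[Title]
 written by lapnet
[Atoms] AU
C      1    6  0.0000000000000000e+00  0.0000000000000000e+00  0.0000000000000000e+00
O      2    8  2.3054657060919999e+00  0.0000000000000000e+00  0.0000000000000000e+00
H      3    1 -1.0393492937300000e+00  1.7385479095120000e+00  5.6691779657999997e-01
H      4    1 -1.0393492937300000e+00 -1.7385479095120000e+00 -5.6691779657999997e-01
[GTO]
   1 0
 s    1 1.00
   1.0000000000000000e+01  1.0000000000000000e+00
 s    1 1.00
   4.5000000000000001e-01  1.0000000000000000e+00

   2 0
 s    1 1.00
   1.8000000000000000e+01  1.0000000000000000e+00
 s    1 1.00
   6.5000000000000002e-01  1.0000000000000000e+00

   3 0
 s    1 1.00
   2.9999999999999999e-01  1.0000000000000002e+00

   4 0
 s    1 1.00
   2.9999999999999999e-01  1.0000000000000002e+00

[MO]
 Sym= A
 Ene= 1
 Spin= Alpha
 Occup=  2.0000000000000000e+00
     1  1.0000000000000000e+00
     2  0.0000000000000000e+00
     3  0.0000000000000000e+00
     4  0.0000000000000000e+00
     5  0.0000000000000000e+00
     6  0.0000000000000000e+00
 Sym= A
 Ene= 2
 Spin= Alpha
 Occup=  2.0000000000000000e+00
     1  0.0000000000000000e+00
     2  1.0000000000000000e+00
     3  0.0000000000000000e+00
     4  0.0000000000000000e+00
     5  0.0000000000000000e+00
     6  0.0000000000000000e+00
 Sym= A
 Ene= 3
 Spin= Alpha
 Occup=  2.0000000000000000e+00
     1  0.0000000000000000e+00
     2  1.0000000000000000e+00
     3  0.0000000000000000e+00
     4  0.0000000000000000e+00
     5  0.0000000000000000e+00
     6  0.0000000000000000e+00
 Sym= A
 Ene= 4
 Spin= Alpha
 Occup=  2.0000000000000000e+00
     1  0.0000000000000000e+00
     2  0.0000000000000000e+00
     3  1.0000000000000000e+00
     4  0.0000000000000000e+00
     5  0.0000000000000000e+00
     6  0.0000000000000000e+00
 Sym= A
 Ene= 5
 Spin= Alpha
 Occup=  2.0000000000000000e+00
     1  0.0000000000000000e+00
     2  0.0000000000000000e+00
     3  0.0000000000000000e+00
     4  1.0000000000000000e+00
     5  0.0000000000000000e+00
     6  0.0000000000000000e+00
 Sym= A
 Ene= 6
 Spin= Alpha
 Occup=  2.0000000000000000e+00
     1  0.0000000000000000e+00
     2  0.0000000000000000e+00
     3  0.0000000000000000e+00
     4  1.0000000000000000e+00
     5  0.0000000000000000e+00
     6  0.0000000000000000e+00
 Sym= A
 Ene= 7
 Spin= Alpha
 Occup=  2.0000000000000000e+00
     1  0.0000000000000000e+00
     2  0.0000000000000000e+00
     3  0.0000000000000000e+00
     4  1.0000000000000000e+00
     5  0.0000000000000000e+00
     6  0.0000000000000000e+00
 Sym= A
 Ene= 8
 Spin= Alpha
 Occup=  1.0000000000000000e+00
     1  0.0000000000000000e+00
     2  0.0000000000000000e+00
     3  0.0000000000000000e+00
     4  0.0000000000000000e+00
     5  1.0000000000000000e+00
     6  0.0000000000000000e+00
 Sym= A
 Ene= 9
 Spin= Alpha
 Occup=  1.0000000000000000e+00
     1  0.0000000000000000e+00
     2  0.0000000000000000e+00
     3  0.0000000000000000e+00
     4  0.0000000000000000e+00
     5  0.0000000000000000e+00
     6  1.0000000000000000e+00
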