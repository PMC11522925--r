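ATOM      1  CA  SER A   1       1.000  -1.200   2.600  1.00  0.00           C  
ATOM      2  OG  SER A   1       0.300  -0.500   2.000  1.00  0.00           O  
ATOM      3  HN1 GLY A   2       2.000   0.500   1.000  1.00  0.00           H  
ATOM      4  HN2 GLY A   3      -2.000   0.500   1.000  1.00  0.00           H  
ATOM      5  C1  PET B  10       0.000   0.000   0.000  1.00  0.00           C  
ATOM      6  O1  PET B  10       1.230   0.000   0.000  1.00  0.00           O  
ATOM      7  OE  PET B  10      -0.600   1.200   0.000  1.00  0.00           O  
END   
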