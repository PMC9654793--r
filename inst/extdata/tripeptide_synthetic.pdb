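REMARK   6 hingedock protonated receptor model
ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N  
ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C  
ATOM      3  C   ALA A   1       2.005  -1.091  -0.915  1.00  0.00           C  
ATOM      4  O   ALA A   1       1.532  -2.227  -0.893  1.00  0.00           O  
ATOM      5  CB  ALA A   1       1.975  -0.190   1.427  1.00  0.00           C  
ATOM      6  N   GLU A   2       3.002  -0.737  -1.719  1.00  0.00           N  
ATOM      7  CA  GLU A   2       3.614  -1.684  -2.643  1.00  0.00           C  
ATOM      8  C   GLU A   2       5.127  -1.498  -2.693  1.00  0.00           C  
ATOM      9  O   GLU A   2       5.622  -0.374  -2.773  1.00  0.00           O  
ATOM     10  CB  GLU A   2       3.007  -1.513  -4.037  1.00  0.00           C  
ATOM     11  CG  GLU A   2       3.615  -2.485  -5.050  1.00  0.00           C  
ATOM     12  CD  GLU A   2       3.012  -2.315  -6.435  1.00  0.00           C  
ATOM     13  OE1 GLU A   2       2.129  -1.443  -6.587  1.00  0.00           O  
ATOM     14  OE2 GLU A   2       3.428  -3.055  -7.351  1.00  0.00           O  
ATOM     15  N   LYS A   3       5.856  -2.609  -2.645  1.00  0.00           N  
ATOM     16  CA  LYS A   3       7.313  -2.570  -2.685  1.00  0.00           C  
ATOM     17  C   LYS A   3       7.866  -3.699  -3.549  1.00  0.00           C  
ATOM     18  O   LYS A   3       7.426  -4.844  -3.447  1.00  0.00           O  
ATOM     19  CB  LYS A   3       7.872  -2.661  -1.264  1.00  0.00           C  
ATOM     20  CG  LYS A   3       9.401  -2.626  -1.245  1.00  0.00           C  
ATOM     21  CD  LYS A   3       9.960  -2.716   0.176  1.00  0.00           C  
ATOM     22  CE  LYS A   3      11.489  -2.681   0.194  1.00  0.00           C  
ATOM     23  NZ  LYS A   3      12.033  -2.769   1.579  1.00  0.00           N  
END   
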