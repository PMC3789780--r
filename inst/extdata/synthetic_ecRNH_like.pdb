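HEADER    SYNTHETIC HANDLE-REGION DEMONSTRATION STRUCTURE
REMARK    SYNTHETIC COORDINATES FOR EXAMPLES AND TESTS (NOT A REAL PDB ENTRY)
HELIX    1   B GLN A   71  TRP A   80  1                                  10
HELIX    2   C HIS A   81  ARG A   88  1                                   8
ATOM      1  CA  MET A  71       2.459   1.484   3.780  1.00  0.00           C
ATOM      2  CA  MET A  72       4.683   2.877   3.144  1.00  0.00           C
ATOM      3  CA  LEU A  73       6.495   4.090   2.161  1.00  0.00           C
ATOM      4  CA  THR A  74       7.819   5.049   0.941  1.00  0.00           C
ATOM      5  CA  SER A  75       8.697   5.694  -0.383  1.00  0.00           C
ATOM      6  CA  ASN A  76       9.282   5.985  -1.665  1.00  0.00           C
ATOM      7  CA  TYR A  77       9.798   5.904  -2.763  1.00  0.00           C
ATOM      8  CA  TRP A  78      10.486   5.456  -3.557  1.00  0.00           C
ATOM      9  CA  ASP A  79      11.545   4.668  -3.960  1.00  0.00           C
ATOM     10  CA  ASP A  80      13.082   3.591  -3.927  1.00  0.00           C
ATOM     11  CA  GLY A  80b     15.089   2.290  -3.461  1.00  0.00           C
ATOM     12  CA  LEU A  81      17.441   0.847  -2.615  1.00  0.00           C
ATOM     13  CA  ARG A  82      19.930  -0.649  -1.480  1.00  0.00           C
ATOM     14  CA  THR A  83      22.314  -2.105  -0.183  1.00  0.00           C
ATOM     15  CA  GLU A  84      24.376  -3.429   1.135  1.00  0.00           C
ATOM     16  CA  TRP A  85      25.979  -4.541   2.327  1.00  0.00           C
ATOM     17  CA  ILE A  86      27.097  -5.370   3.264  1.00  0.00           C
ATOM     18  CA  TRP A  87      27.824  -5.865   3.841  1.00  0.00           C
ATOM     19  CA  ARG A  88      28.350  -5.996   3.995  1.00  0.00           C
ATOM     20  CA  SER A  89      28.912  -5.754   3.709  1.00  0.00           C
ATOM     21  CA  ASN A  90      29.741  -5.154   3.016  1.00  0.00           C
ATOM     22  CA  MET A  91      31.000  -4.233   1.990  1.00  0.00           C
ATOM     23  CA  ILE A  92      32.749  -3.050   0.745  1.00  0.00           C
ATOM     24  CA  ALA A  93      34.927  -1.676  -0.582  1.00  0.00           C
ATOM     25  CA  SER A  94      37.367  -0.199  -1.845  1.00  0.00           C
ATOM     26  CA  ASP A  95      39.840   1.291  -2.905  1.00  0.00           C
ATOM     27  CA  TYR A  96      42.108   2.700  -3.645  1.00  0.00           C
ATOM     28  CA  ASP A  97      43.981   3.942  -3.983  1.00  0.00           C
ATOM     29  CA  ALA A  98      45.370   4.938  -3.884  1.00  0.00           C
ATOM     30  CA  ALA A  99      46.301   5.628  -3.356  1.00  0.00           C
ATOM     31  CA  TRP A 100      46.913   5.968  -2.460  1.00  0.00           C
ATOM     32  CA  GLY A 101      47.424   5.936  -1.292  1.00  0.00           C
END
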