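REMARK synthetic three-residue fixture (Lys-Gly-Glu), hand-written
ATOM      1  N   LYS A   1       0.000   0.000   0.000  1.00 10.00           N
ATOM      2  CA  LYS A   1       1.458   0.000   0.000  1.00 10.00           C
ATOM      3  C   LYS A   1       2.009   1.420   0.000  1.00 10.00           C
ATOM      4  O   LYS A   1       1.251   2.390   0.000  1.00 10.00           O
ATOM      5  CB  LYS A   1       1.986  -0.773  -1.215  1.00 10.00           C
ATOM      6  CG  LYS A   1       3.504  -0.888  -1.265  1.00 10.00           C
ATOM      7  CD  LYS A   1       3.998  -1.681  -2.466  1.00 10.00           C
ATOM      8  CE  LYS A   1       5.515  -1.796  -2.516  1.00 10.00           C
ATOM      9  NZ  LYS A   1       6.009  -2.588  -3.717  1.00 10.00           N
ATOM     10  N   GLY A   2       3.332   1.536   0.000  1.00 10.00           N
ATOM     11  CA  GLY A   2       3.982   2.839   0.000  1.00 10.00           C
ATOM     12  C   GLY A   2       5.496   2.719   0.000  1.00 10.00           C
ATOM     13  O   GLY A   2       6.041   1.613   0.000  1.00 10.00           O
ATOM     14  N   GLU A   3       6.193   3.851   0.000  1.00 10.00           N
ATOM     15  CA  GLU A   3       7.651   3.851   0.000  1.00 10.00           C
ATOM     16  C   GLU A   3       8.202   5.271   0.000  1.00 10.00           C
ATOM     17  O   GLU A   3       7.444   6.241   0.000  1.00 10.00           O
ATOM     18  CB  GLU A   3       8.179   3.078  -1.215  1.00 10.00           C
ATOM     19  CG  GLU A   3       9.697   2.963  -1.265  1.00 10.00           C
ATOM     20  CD  GLU A   3      10.191   2.170  -2.466  1.00 10.00           C
ATOM     21  OE1 GLU A   3       9.414   1.604  -3.241  1.00 10.00           O
ATOM     22  OE2 GLU A   3      11.428   2.093  -2.601  1.00 10.00           O
END
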