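ATOM      1  N   ASN A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  ASN A   1       1.458   0.000   0.000  1.00  0.00           C
ATOM      3  C   ASN A   1       2.009   1.422   0.000  1.00  0.00           C
ATOM      4  N   PRO A   2       3.236   1.576   0.489  1.00  0.00           N
ATOM      5  CA  PRO A   2       3.879   2.883   0.546  1.00  0.00           C
ATOM      6  C   PRO A   2       4.244   3.379  -0.849  1.00  0.00           C
ATOM      7  N   ASN A   3       3.964   4.652  -1.110  1.00  0.00           N
ATOM      8  CA  ASN A   3       4.263   5.251  -2.406  1.00  0.00           C
ATOM      9  C   ASN A   3       5.747   5.575  -2.535  1.00  0.00           C
ATOM     10  N   GLY A   4       6.279   5.422  -3.743  1.00  0.00           N
ATOM     11  CA  GLY A   4       7.687   5.698  -4.002  1.00  0.00           C
ATOM     12  C   GLY A   4       8.004   7.177  -3.805  1.00  0.00           C
ATOM     13  N   SER A   5       9.203   7.458  -3.306  1.00  0.00           N
ATOM     14  CA  SER A   5       9.631   8.832  -3.069  1.00  0.00           C
ATOM     15  C   SER A   5       9.813   9.587  -4.382  1.00  0.00           C
ATOM     16  N   PRO A   6       9.578  10.894  -4.344  1.00  0.00           N
ATOM     17  CA  PRO A   6       9.715  11.732  -5.529  1.00  0.00           C
ATOM     18  C   PRO A   6      11.169  12.132  -5.756  1.00  0.00           C
ATOM     19  N   LEU A   7      11.514  12.401  -7.011  1.00  0.00           N
ATOM     20  CA  LEU A   7      12.873  12.795  -7.364  1.00  0.00           C
ATOM     21  C   LEU A   7      13.341  13.976  -6.520  1.00  0.00           C
ATOM     22  N   LEU A   8      12.389  14.774  -6.048  1.00  0.00           N
ATOM     23  CA  LEU A   8      12.702  15.938  -5.228  1.00  0.00           C
ATOM     24  C   LEU A   8      13.395  15.529  -3.932  1.00  0.00           C
ATOM     25  N   GLN A   9      12.845  14.520  -3.266  1.00  0.00           N
ATOM     26  CA  GLN A   9      13.408  14.031  -2.013  1.00  0.00           C
ATOM     27  C   GLN A   9      14.879  13.662  -2.177  1.00  0.00           C
ATOM     28  N   GLN A  10      15.186  12.933  -3.245  1.00  0.00           N
ATOM     29  CA  GLN A  10      16.555  12.514  -3.518  1.00  0.00           C
ATOM     30  C   GLN A  10      17.430  13.703  -3.900  1.00  0.00           C
ATOM     31  N   GLN A  11      16.848  14.650  -4.629  1.00  0.00           N
ATOM     32  CA  GLN A  11      17.573  15.839  -5.061  1.00  0.00           C
ATOM     33  C   GLN A  11      17.771  16.814  -3.905  1.00  0.00           C
ATOM     34  N   GLU A  12      16.721  17.009  -3.115  1.00  0.00           N
ATOM     35  CA  GLU A  12      16.777  17.916  -1.975  1.00  0.00           C
ATOM     36  C   GLU A  12      17.908  17.537  -1.025  1.00  0.00           C
ATOM     37  N   ARG A  13      18.209  16.244  -0.956  1.00  0.00           N
ATOM     38  CA  ARG A  13      19.269  15.749  -0.087  1.00  0.00           C
ATOM     39  C   ARG A  13      20.636  16.246  -0.546  1.00  0.00           C
ATOM     40  N   MET A  14      20.925  16.064  -1.831  1.00  0.00           N
ATOM     41  CA  MET A  14      22.198  16.493  -2.398  1.00  0.00           C
ATOM     42  C   MET A  14      22.340  18.010  -2.348  1.00  0.00           C
ATOM     43  N   GLN A  15      21.220  18.710  -2.495  1.00  0.00           N
ATOM     44  CA  GLN A  15      21.218  20.168  -2.467  1.00  0.00           C
ATOM     45  C   GLN A  15      21.848  20.696  -1.182  1.00  0.00           C
ATOM     46  N   ARG A  16      21.360  20.208  -0.046  1.00  0.00           N
ATOM     47  CA  ARG A  16      21.874  20.630   1.252  1.00  0.00           C
ATOM     48  C   ARG A  16      23.313  20.167   1.452  1.00  0.00           C
ATOM     49  N   GLN A  17      23.685  19.091   0.765  1.00  0.00           N
ATOM     50  CA  GLN A  17      25.033  18.546   0.865  1.00  0.00           C
ATOM     51  C   GLN A  17      26.058  19.492   0.250  1.00  0.00           C
ATOM     52  N   LYS A  18      25.704  20.083  -0.886  1.00  0.00           N
ATOM     53  CA  LYS A  18      26.592  21.011  -1.577  1.00  0.00           C
ATOM     54  C   LYS A  18      27.088  22.104  -0.636  1.00  0.00           C
ATOM     55  N   GLN A  19      26.176  22.646   0.165  1.00  0.00           N
ATOM     56  CA  GLN A  19      26.519  23.700   1.112  1.00  0.00           C
ATOM     57  C   GLN A  19      27.544  23.215   2.131  1.00  0.00           C
ATOM     58  N   ALA A  20      27.320  22.018   2.665  1.00  0.00           N
ATOM     59  CA  ALA A  20      28.223  21.437   3.651  1.00  0.00           C
ATOM     60  C   ALA A  20      29.662  21.436   3.148  1.00  0.00           C
ATOM     61  N   LYS A  21      29.828  21.236   1.844  1.00  0.00           N
ATOM     62  CA  LYS A  21      31.152  21.211   1.235  1.00  0.00           C
ATOM     63  C   LYS A  21      31.716  22.620   1.083  1.00  0.00           C
ATOM     64  N   ARG A  22      30.846  23.567   0.748  1.00  0.00           N
ATOM     65  CA  ARG A  22      31.255  24.955   0.570  1.00  0.00           C
ATOM     66  C   ARG A  22      31.637  25.592   1.902  1.00  0.00           C
ATOM     67  N   PHE A  23      30.832  25.334   2.928  1.00  0.00           N
ATOM     68  CA  PHE A  23      31.085  25.881   4.256  1.00  0.00           C
ATOM     69  C   PHE A  23      31.104  24.780   5.311  1.00  0.00           C
ATOM     70  N   THR A  24      32.136  24.790   6.150  1.00  0.00           N
ATOM     71  CA  THR A  24      32.275  23.793   7.205  1.00  0.00           C
ATOM     72  C   THR A  24      32.282  24.446   8.583  1.00  0.00           C
ATOM     73  N   TRP A  25      31.397  23.980   9.458  1.00  0.00           N
ATOM     74  CA  TRP A  25      31.300  24.517  10.810  1.00  0.00           C
ATOM     75  C   TRP A  25      31.485  23.420  11.853  1.00  0.00           C
END
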