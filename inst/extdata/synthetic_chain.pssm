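
Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts
             A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 N  -2  -1   5  -1   2   0  -1   0   2  -1  -2  -1   1   0   0  -2  -1   3   0  -2   0   0
    2 P  -1  -1   0  -1   2   0  -1  -2   2  -1  -2  -1   2   0   5  -2  -1   3   1  -1   0   0
    3 N  -2  -1   5  -1   2   0  -1  -2   2  -1  -2  -1   1   0  -1  -2  -1   3   0  -2   0   0
    4 G  -1  -1  -1   0   2   0  -1   4   2  -1  -3  -1   1   0  -1  -2  -1   3   0  -2   0   0
    5 S  -2  -1   0  -1   2   0  -1  -2   2  -1  -2  -1   2   0  -1   4  -1   3   0  -2   0   0
    6 P  -2  -1  -1  -1   2   0  -1  -2   2   0  -3  -1   1   0   5   0  -1   3   0  -2   0   0
    7 L  -2  -1  -1  -1   2   0  -2  -2   1  -1   3  -1   1   0  -1   1  -1   3   0  -2   0   0
    8 L  -2  -1   0  -1   2   0  -1  -2   2  -1   3  -1   2   0  -1  -2  -1   3   0  -2   0   0
    9 Q  -2  -1  -1  -1   2   5  -1  -2   2  -1  -3  -1   1   0  -1   1  -1   3   0  -2   0   0
   10 Q  -2  -1  -1  -1   2   6  -1  -2   2  -1  -3  -1   1   0  -1  -2  -1   3   0  -2   0   0
   11 Q  -2  -1   0   0   2   5  -1  -2   2   0  -2  -1   2   0  -1  -2  -1   3   1  -1   0   0
   12 E  -2  -1   0  -1   2   0   4  -2   2  -1  -2  -1   2   0   0  -2  -1   3   0  -2   0   0
   13 R  -1   5  -1  -1   2   0  -1  -2   2  -1  -3  -1   1   0  -1  -2  -1   3   0  -2   0   0
   14 M  -2  -1  -1  -1   2   0   0  -1   1  -1  -3  -1   7   0  -1  -2  -1   3   0  -2   0   0
   15 Q  -2  -1  -1  -1   2   5  -2  -1   1  -1  -3  -1   1   0  -1  -2   0   3   0  -2   0   0
   16 R  -2   5  -1  -1   2   0  -2  -2   1  -1  -3   0   1   0  -1  -2  -1   3   0  -1   0   0
   17 Q  -1  -1  -1  -1   2   5  -2  -2   1  -1  -3   0   1   0  -1  -2  -1   3   0  -1   0   0
   18 K  -1  -1   0  -1   2   0  -1  -2   2  -1  -2   4   2   0  -1  -2  -1   3   0  -2   0   0
   19 Q  -2  -1  -1  -1   2   5  -2  -2   1  -1  -3  -1   1   1   0  -2  -1   3   0  -2   0   0
   20 A   3  -1   0  -1   2   0  -1  -2   2  -1  -2  -1   2   2  -1   0  -1   3   0  -2   0   0
   21 K  -2  -1   0  -1   2   0  -1  -2   2  -1  -2   4   2   1   0  -2  -1   3   1  -1   0   0
   22 R  -1   4  -1  -1   2   2  -1  -2   2  -1  -3  -1   3   0  -1  -2  -1   3   0  -2   0   0
   23 F  -2  -1  -1  -1   2   0  -2  -2   1  -1  -3  -1   1   6  -1  -2  -1   3   0  -2   0   0
   24 T  -2  -1  -1  -1   2   0  -1  -2   2  -1  -3  -1   1   0  -1  -1   4   3   0  -1   0   0
   25 W  -2  -1  -1  -1   2   0  -1  -2   2   0  -2  -1   3   0  -1  -2  -1   8   0  -2   0   0

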