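
Last position-specific scoring matrix computed, weighted, and normalized
              A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V   A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 M    1   2   3   4   5   6   7   8   9  10  11  12  13  14  15  16  17  18  19  20   15   0  11  21  21  20   2   9  29   1   5  12  19   3  30   3   8  17  23  29  0.82 0.59
    2 K    6   7  -3   7  -6   0  -5   0  -1   7  -2   1   0   3  -1  -2   7   5   3  -6   13  27  30  21  30   5   6  14  19  20  14   6  16  26  21  28  12  11  24   8  0.84 0.09
    3 V    1   0  -3  -4  -1   4   1   0  -4   4  -1   4  -5   6  -3   0   6   4  -5   0    9  27   2  26  25   9  20  23  20  27  14   3  16   7   2   6  24  18  18  23  0.34 0.25
    4 L   -3   7  -4   6   6   0   4  -1   4   3   4   0   1   1  -4   4  -6  -4   0  -3   17   5  14   5   9   0   9  28  17  16  16   5  19  28  21  17   3   3  28  24  0.61 0.55

                      K         Lambda
Standard Ungapped    0.1347     0.3179
Standard Gapped      0.0410     0.2670
PSI Ungapped         0.1802     0.3164
PSI Gapped           0.0410     0.2670
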