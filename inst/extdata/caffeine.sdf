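caffeine
 OpenBabel09302603593D

 24 25  0  0  0  0  0  0  0  0999 V2000
   -3.2466   -1.1353    0.0319 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.2658   -0.0801    0.0052 N   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5218    1.2655   -0.0054 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4089    1.9726   -0.0088 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.4149    1.0401   -0.0027 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.9091   -0.2284    0.0004 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0853   -1.3861    0.0050 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5415   -2.5254    0.0049 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.2782   -1.0794    0.0098 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.2247   -2.1774    0.0215 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.8292    0.2186    0.0070 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.0524    0.3879    0.0088 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.9365    1.2911    0.0033 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.4261    2.6576    0.0096 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.2500   -0.7023    0.0055 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.1156   -1.7061    0.9546 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.0980   -1.7730   -0.8427 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.5247    1.6736   -0.0079 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.7355   -3.1545    0.0226 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8529   -2.0946    0.9145 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8675   -2.1029   -0.8618 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.5179    2.6993    0.0365 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.0366    3.1737    0.8931 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.0794    3.1659   -0.8957 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1 15  1  0  0  0  0
  1 16  1  0  0  0  0
  1 17  1  0  0  0  0
  2  3  1  0  0  0  0
  2  6  1  0  0  0  0
  3  4  2  0  0  0  0
  3 18  1  0  0  0  0
  4  5  1  0  0  0  0
  5  6  2  0  0  0  0
  5 13  1  0  0  0  0
  6  7  1  0  0  0  0
  7  8  2  0  0  0  0
  7  9  1  0  0  0  0
  9 10  1  0  0  0  0
  9 11  1  0  0  0  0
 10 19  1  0  0  0  0
 10 20  1  0  0  0  0
 10 21  1  0  0  0  0
 11 12  2  0  0  0  0
 11 13  1  0  0  0  0
 13 14  1  0  0  0  0
 14 22  1  0  0  0  0
 14 23  1  0  0  0  0
 14 24  1  0  0  0  0
M  END
$$$$
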