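acetate
 OpenBabel09302603593D

  7  6  0  0  0  0  0  0  0  0999 V2000
    0.9769   -0.0534    0.0451 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.4956   -0.0721    0.0291 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.0532    0.7879    0.7658 O   0  0  0  0  0  0  0  0  0  0  0  0
    3.0065   -0.9494   -0.7224 O   0  5  0  0  0  0  0  0  0  0  0  0
    0.5951    0.7254    0.7122 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.5978   -1.0203    0.3894 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.5978    0.1384   -0.9631 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  5  1  0  0  0  0
  1  6  1  0  0  0  0
  1  7  1  0  0  0  0
  2  3  2  0  0  0  0
  2  4  1  0  0  0  0
M  CHG  1   4  -1
M  END
$$$$
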